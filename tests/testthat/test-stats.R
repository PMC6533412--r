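# Discriminant boundary, two-group MANOVA, and diagnostic metrics.

two_clouds <- function(n = 20L, mu1 = c(3, 0), mu0 = c(-3, 0), sd = 1,
                       seed = 1L) {
  set.seed(seed)
  lab <- rep(c(TRUE, FALSE), each = n)
  x <- rbind(cbind(rnorm(n, mu1[1], sd), rnorm(n, mu1[2], sd)),
             cbind(rnorm(n, mu0[1], sd), rnorm(n, mu0[2], sd)))
  list(x = x, labels = lab)
}

test_that("LDA boundary is perpendicular to the mean axis for isotropic data", {
  d <- two_clouds(n = 200L, mu1 = c(2, 1), mu0 = c(-1, -2), seed = 2L)
  b <- fit_lda(d$x, d$labels)
  # normal direction (L1, L2) is anti-parallel to mu1 - mu0 for isotropic
  # covariance (the minus sign comes from the metastatic-negative convention)
  mu_diff <- colMeans(d$x[d$labels, ]) - colMeans(d$x[!d$labels, ])
  v <- c(b$L1, b$L2)
  cos_angle <- sum(v * mu_diff) / sqrt(sum(v^2) * sum(mu_diff^2))
  expect_equal(cos_angle, -1, tolerance = 0.05)
  # metastatic class mean lies strictly on the negative side
  mu1 <- colMeans(d$x[d$labels, ])
  expect_lt(b$K + b$L1 * mu1[1] + b$L2 * mu1[2], 0)
})

test_that("label swap flips coefficients; translation shifts only K", {
  d <- two_clouds(seed = 3L)
  b <- fit_lda(d$x, d$labels)
  bs <- fit_lda(d$x, !d$labels)
  expect_equal(c(bs$K, bs$L1, bs$L2), -c(b$K, b$L1, b$L2))
  # every off-boundary point keeps its class partition (inverted labels)
  pred <- classify(b, d$x[, 1], d$x[, 2])
  pred_s <- classify(bs, d$x[, 1], d$x[, 2])
  expect_identical(pred_s, !pred)
  tr <- c(5, -2)
  bt <- fit_lda(sweep(d$x, 2, -tr), d$labels)  # translate by +tr
  expect_equal(c(bt$L1, bt$L2), c(b$L1, b$L2))
  expect_equal(bt$K, b$K - (b$L1 * tr[1] + b$L2 * tr[2]))
})

test_that("fit_lda agrees with an independent reference implementation", {
  skip_if_not_installed("MASS")
  d <- two_clouds(n = 15L, mu1 = c(1.5, 0.5), mu0 = c(0, 0), seed = 4L)
  b <- fit_lda(d$x, d$labels)
  ours <- classify(b, d$x[, 1], d$x[, 2])
  fit <- MASS::lda(x = d$x, grouping = d$labels)
  ref <- as.logical(as.character(predict(fit, d$x)$class))
  expect_identical(ours, ref)
})

test_that("classify applies the strict negative half-plane rule", {
  b <- discriminant_boundary(K = 40.90, L1 = -7.75, L2 = 6.25)
  expect_true(classify(b, 7.0, 1.0))    # 40.90 - 54.25 + 6.25 < 0
  expect_false(classify(b, 4.0, 1.0))   # 40.90 - 31.00 + 6.25 > 0
  # a point exactly on the boundary is non-metastatic
  x1 <- 5; x2 <- (-b$K - b$L1 * x1) / b$L2
  expect_false(classify(b, x1, x2))
  # positive rescaling leaves the rule untouched
  b2 <- discriminant_boundary(K = 3 * b$K, L1 = 3 * b$L1, L2 = 3 * b$L2)
  g <- expand.grid(x1 = seq(0, 10, 0.5), x2 = seq(-5, 5, 0.5))
  expect_identical(classify(b2, g$x1, g$x2), classify(b, g$x1, g$x2))
})

test_that("two-group MANOVA matches its algebraic identities", {
  d <- two_clouds(n = 10L, mu1 = c(1, 0.5), mu0 = c(0, 0), seed = 5L)
  mv <- manova_two_group(d$x, d$labels)
  expect_true(mv$wilks_lambda > 0 && mv$wilks_lambda <= 1)
  # Wilks' lambda <-> Hotelling T2
  n <- nrow(d$x)
  expect_equal(mv$wilks_lambda, 1 / (1 + mv$hotelling_t2 / (n - 2)),
               tolerance = 1e-12)
  # d = 1 reduces to the pooled-variance t-test, F = t^2
  v <- d$x[, 1, drop = FALSE]
  mv1 <- manova_two_group(v, d$labels)
  tt <- t.test(v[d$labels], v[!d$labels], var.equal = TRUE)
  expect_equal(mv1$f_stat, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(mv1$p_value, tt$p.value, tolerance = 1e-10)
  # agreement with stats::manova's Wilks statistic
  fit <- stats::manova(d$x ~ d$labels)
  wl <- summary(fit, test = "Wilks")$stats[1, "Wilks"]
  expect_equal(mv$wilks_lambda, unname(wl), tolerance = 1e-10)
  # identical class means: no separation
  same <- rbind(d$x[1:10, ], d$x[1:10, ])
  mv_same <- manova_two_group(same, rep(c(TRUE, FALSE), each = 10))
  expect_gt(mv_same$wilks_lambda, 0.999)
  expect_gt(mv_same$p_value, 0.999)
  # degenerate covariance errors out
  sing <- cbind(1:20, 1:20)
  expect_error(manova_two_group(sing, d$labels), "degenerate")
})

test_that("MANOVA keeps its nominal type-I error on Gaussian nulls", {
  set.seed(17)
  hits <- 0L
  reps <- 1000L
  for (r in seq_len(reps)) {
    x <- cbind(rnorm(20), rnorm(20))
    p <- manova_two_group(x, rep(c(TRUE, FALSE), each = 10))$p_value
    if (p < 0.05) hits <- hits + 1L
  }
  expect_gt(hits / reps, 0.035)
  expect_lt(hits / reps, 0.065)
})

test_that("confusion metrics reproduce their defining ratios", {
  cm <- confusion_matrix(tp = 8, fp = 2, tn = 8, fn = 2)
  expect_equal(unname(confusion_metrics(cm)), rep(80, 5))
  cm2 <- confusion_matrix(tp = 3, fp = 2, tn = 8, fn = 7)
  m2 <- confusion_metrics(cm2)
  expect_equal(unname(m2["npv"]), 100 * 8 / 15)
  # zero denominators become missing, not infinities
  cm3 <- confusion_matrix(tp = 0, fp = 0, tn = 5, fn = 5)
  m3 <- confusion_metrics(cm3)
  expect_true(is.na(m3["ppv"]))
  expect_equal(unname(m3["acc"]), 50)
  # ACC is recoverable from SN, SP and the class sizes
  recompute <- (m2["sn"] / 100 * 10 + m2["sp"] / 100 * 10) / 20 * 100
  expect_equal(unname(m2["acc"]), unname(recompute))
  expect_error(confusion_matrix(0, 0, 0, 0), "not all zero")
})
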