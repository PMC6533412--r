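# Supervised end of the pipeline: the linear discriminant boundary in the
# (e_ADC, e_SUV) plane, two-group MANOVA via Wilks' lambda, and the
# diagnostic confusion metrics.

#' Confusion matrix of counts
#'
#' @param tp,fp,tn,fn non-negative integer counts; at least one positive.
#' @return An object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != round(counts)) || sum(counts) < 1)
    stop("confusion counts must be non-negative integers, not all zero",
         call. = FALSE)
  structure(as.list(counts), class = "confusion_matrix")
}

confusion_from_prediction <- function(predicted, actual) {
  confusion_matrix(tp = sum(predicted & actual),
                   fp = sum(predicted & !actual),
                   tn = sum(!predicted & !actual),
                   fn = sum(!predicted & actual))
}

#' Diagnostic metrics from a confusion matrix
#'
#' Sensitivity, specificity, positive/negative predictive value and accuracy
#' as percentages at full precision; any metric with a zero denominator is
#' `NA`. Use `round()` on the result for integer-percent presentation.
#'
#' @param cm a [confusion_matrix].
#' @return Named numeric vector `sn, sp, ppv, npv, acc` (percent).
#' @export
confusion_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  ratio <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  with(cm, c(sn = ratio(tp, tp + fn), sp = ratio(tn, tn + fp),
             ppv = ratio(tp, tp + fp), npv = ratio(tn, tn + fn),
             acc = ratio(tp + tn, tp + fp + tn + fn)))
}

#' Fit a two-class linear discriminant boundary
#'
#' Classical LDA with pooled within-class covariance and empirical priors.
#' The boundary is reported in the form `K + L1*x1 + L2*x2 = 0`, with the
#' sign convention that the metastatic class occupies the strictly negative
#' half-plane; by construction the metastatic class mean always satisfies
#' `K + L1*x1 + L2*x2 < 0`. In the headline entropy-pair application `x1` is
#' the ADC GLCM entropy and `x2` the SUV GLCM entropy.
#'
#' @param points numeric n x 2 matrix (columns `x1`, `x2`).
#' @param labels logical vector; `TRUE` = metastatic.
#' @return An object of class `discriminant_boundary` with fields `K`, `L1`,
#'   `L2`.
#' @export
fit_lda <- function(points, labels) {
  points <- as.matrix(points)
  labels <- as.logical(labels)
  stopifnot(ncol(points) == 2L, nrow(points) == length(labels),
            !anyNA(points), !anyNA(labels))
  n1 <- sum(labels); n0 <- sum(!labels); n <- n1 + n0
  if (n1 < 2L || n0 < 2L)
    stop("need at least 2 cases per class", call. = FALSE)
  mu1 <- colMeans(points[labels, , drop = FALSE])
  mu0 <- colMeans(points[!labels, , drop = FALSE])
  s1 <- stats::cov(points[labels, , drop = FALSE])
  s0 <- stats::cov(points[!labels, , drop = FALSE])
  sp <- ((n1 - 1) * s1 + (n0 - 1) * s0) / (n - 2)
  w <- tryCatch(solve(sp, mu1 - mu0),
                error = function(e)
                  stop("singular pooled covariance", call. = FALSE))
  # discriminant difference: w'x - c > 0 <=> metastatic
  c0 <- 0.5 * sum((mu1 + mu0) * w) - log(n1 / n0)
  discriminant_boundary(K = c0, L1 = -w[1], L2 = -w[2])
}

#' @rdname fit_lda
#' @param K,L1,L2 boundary coefficients; `(L1, L2)` must not both be zero.
#' @export
discriminant_boundary <- function(K, L1, L2) {
  stopifnot(is.finite(K), is.finite(L1), is.finite(L2))
  if (L1 == 0 && L2 == 0)
    stop("(L1, L2) must not both be zero", call. = FALSE)
  structure(list(K = unname(K), L1 = unname(L1), L2 = unname(L2)),
            class = "discriminant_boundary")
}

#' @export
print.discriminant_boundary <- function(x, ...) {
  cat(sprintf("<discriminant_boundary> %.4g %+.4g*x1 %+.4g*x2 = 0 (metastatic: < 0)\n",
              x$K, x$L1, x$L2))
  invisible(x)
}

#' Classify points against a discriminant boundary
#'
#' A point is metastatic iff `K + L1*x1 + L2*x2 < 0` (strict); points
#' exactly on the boundary are non-metastatic.
#'
#' @param boundary a `discriminant_boundary`.
#' @param x1,x2 numeric vectors of coordinates (recycled pairwise).
#' @return Logical vector, `TRUE` = metastatic.
#' @export
classify <- function(boundary, x1, x2) {
  stopifnot(inherits(boundary, "discriminant_boundary"),
            all(is.finite(x1)), all(is.finite(x2)))
  boundary$K + boundary$L1 * x1 + boundary$L2 * x2 < 0
}

#' Two-group MANOVA (Wilks' lambda)
#'
#' Tests equality of the two class mean vectors. For two groups the exact
#' transform `F = ((n - d - 1)/d) * (1 - lambda)/lambda` on `(d, n - d - 1)`
#' degrees of freedom holds, and Wilks' lambda is equivalent to Hotelling's
#' T-squared via `lambda = 1 / (1 + T2/(n - 2))`.
#'
#' @param points numeric n x d matrix (d = 1 or 2 in this pipeline; any d <
#'   n - 1 is accepted).
#' @param labels logical vector of group membership.
#' @return List with `wilks_lambda`, `hotelling_t2`, `f_stat`, `df1`, `df2`,
#'   `p_value`.
#' @export
manova_two_group <- function(points, labels) {
  points <- as.matrix(points)
  labels <- as.logical(labels)
  n <- nrow(points); d <- ncol(points)
  stopifnot(length(labels) == n, !anyNA(points), !anyNA(labels))
  if (sum(labels) < 2L || sum(!labels) < 2L)
    stop("need at least 2 cases per class", call. = FALSE)
  if (n <= d + 1L) stop("need n > d + 1", call. = FALSE)
  grand <- colMeans(points)
  w <- matrix(0, d, d)
  b <- matrix(0, d, d)
  for (g in c(TRUE, FALSE)) {
    xg <- points[labels == g, , drop = FALSE]
    mg <- colMeans(xg)
    cent <- sweep(xg, 2L, mg)
    w <- w + crossprod(cent)
    b <- b + nrow(xg) * tcrossprod(mg - grand)
  }
  dw <- det(w)
  if (dw <= 0) stop("degenerate within-group covariance", call. = FALSE)
  lambda <- dw / det(w + b)
  lambda <- min(max(lambda, 0), 1)
  df1 <- d
  df2 <- n - d - 1L
  f <- (df2 / df1) * (1 - lambda) / lambda
  list(wilks_lambda = lambda,
       hotelling_t2 = (n - 2) * (1 - lambda) / lambda,
       f_stat = f, df1 = df1, df2 = df2,
       p_value = stats::pf(f, df1, df2, lower.tail = FALSE))
}
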