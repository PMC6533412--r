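# Feature engine: discretization, first-order statistics, GLCM construction,
# second-order features against a brute-force oracle, and the Feret
# diameter.

test_that("discretization follows the fixed-bin-number rule", {
  cfg4 <- discretization_config(n_bins = 4L)
  vm <- vol_with_values(c(0, 1, 2, 3))
  lev <- discretize(vm$image, vm$mask, cfg4)
  expect_identical(lev$levels[1:4], 1:4)
  # constant ROI maps to level 1
  vc <- vol_with_values(rep(5, 6))
  levc <- discretize(vc$image, vc$mask, discretization_config())
  expect_true(all(levc$levels[1:6] == 1L))
  # any ROI stays within 1..Ng and the maximum hits Ng
  set.seed(1)
  vr <- vol_with_values(rnorm(40), dims = c(10L, 2L, 2L))
  levr <- discretize(vr$image, vr$mask, discretization_config(n_bins = 16L))
  inm <- levr$levels[!is.na(levr$levels)]
  expect_true(all(inm >= 1L & inm <= 16L))
  expect_identical(max(inm), 16L)
  expect_error(discretization_config(n_bins = 1L), ">= 2")
})

test_that("first-order features match hand-computed values", {
  vm <- vol_with_values(c(1, 2, 3, 4))
  f <- first_order_features(vm$image, vm$mask, discretization_config(4L))
  expect_equal(unname(f["fo_mean"]), 2.5)
  expect_equal(unname(f["fo_sd"]), sqrt(1.25))
  expect_equal(unname(f["fo_entropy"]), 2)       # 4 bins, p = 1/4 each
  expect_equal(unname(f["fo_uniformity"]), 0.25)
  expect_equal(unname(f["fo_median"]), 2.5)
  expect_equal(unname(f["fo_min"]), 1)
  expect_equal(unname(f["fo_max"]), 4)
  expect_equal(unname(f["fo_skewness"]), 0)      # symmetric multiset
  # excess kurtosis of {-1,-1,1,1} is -2; CoV missing when mean is 0
  v2 <- vol_with_values(c(-1, -1, 1, 1))
  f2 <- first_order_features(v2$image, v2$mask, discretization_config(4L))
  expect_equal(unname(f2["fo_kurtosis"]), -2)
  expect_true(is.na(f2["fo_cov"]))
  # constant ROI degenerates cleanly
  vc <- vol_with_values(rep(3, 5))
  fc <- first_order_features(vc$image, vc$mask, discretization_config())
  expect_equal(unname(fc[c("fo_mean", "fo_sd", "fo_entropy",
                           "fo_uniformity", "fo_cov")]), c(3, 0, 0, 1, 0))
  expect_equal(unname(fc["fo_min"]), unname(fc["fo_max"]))
})

test_that("GLCM counts match hand enumeration and normalize symmetrically", {
  # 2x2x1 level image [[1,1],[2,2]] (x = rows of the array's first axis):
  # pairs by direction within the slice, symmetrized then merged:
  #   x-offset (1,0,0): (1,2),(1,2) -> 12,21 twice each
  #   y-offset (0,1,0): (1,1),(2,2) -> 11,11,22,22
  #   diagonals (1,1,0),(-1,1,0): (1,2),(1,2) -> 12,21 twice each
  vm <- vol_with_values(c(1, 2, 1, 2), dims = c(2L, 2L, 1L))
  lev <- discretize(vm$image, vm$mask, discretization_config(n_bins = 2L))
  g <- compute_glcm(lev)
  counts <- g$p * g$n_pairs
  expect_equal(counts, matrix(c(2, 4, 4, 2), 2, 2))
  expect_equal(sum(g$p), 1)
  expect_equal(g$p, t(g$p))
  # constant ROI: single cell
  vc <- vol_with_values(rep(2, 8), dims = c(2L, 2L, 2L))
  gc <- compute_glcm(discretize(vc$image, vc$mask, discretization_config()))
  expect_equal(gc$p[1, 1], 1)
  # single voxel has no pairs
  v1 <- vol_with_values(1)
  expect_error(compute_glcm(discretize(v1$image, v1$mask,
                                       discretization_config())),
               "degenerate GLCM")
})

test_that("merged GLCM equals the count-weighted mix of directions", {
  set.seed(42)
  vr <- vol_with_values(rnorm(60), dims = c(5L, 4L, 3L))
  lev <- discretize(vr$image, vr$mask, discretization_config(n_bins = 8L))
  merged <- compute_glcm(lev)
  per <- compute_glcm(lev, per_direction = TRUE)
  weights <- vapply(per, `[[`, 0, "n_pairs")
  mix <- Reduce(`+`, Map(function(g, w) g$p * w, per, weights)) /
    sum(weights)
  expect_equal(merged$p, mix, tolerance = 1e-12)
})

test_that("all 12 second-order features equal the brute-force oracle", {
  set.seed(7)
  for (k in 1:50) {
    g <- random_glcm(8L)
    expect_equal(second_order_features(g), brute_force_glcm_features(g$p),
                 tolerance = 1e-10)
  }
})

test_that("degenerate and two-cell matrices give their closed-form values", {
  one <- structure(list(p = matrix(c(1, 0, 0, 0), 2, 2), n_levels = 2L,
                        distance = 1L, n_pairs = 10), class = "glcm_matrix")
  f1 <- second_order_features(one)
  expect_equal(unname(f1[c("glcm_entropy", "glcm_contrast", "glcm_asm",
                           "glcm_joint_max", "glcm_homogeneity",
                           "glcm_correlation")]), c(0, 0, 1, 1, 1, 0))
  two <- structure(list(p = diag(2) / 2, n_levels = 2L, distance = 1L,
                        n_pairs = 10), class = "glcm_matrix")
  f2 <- second_order_features(two)
  expect_equal(unname(f2["glcm_entropy"]), 1)
  expect_equal(unname(f2["glcm_contrast"]), 0)
  expect_equal(unname(f2["glcm_joint_avg"]), 1.5)
  expect_equal(unname(f2["glcm_autocorrelation"]), 2.5)
})

test_that("entropy is permutation-invariant but contrast is not", {
  set.seed(3)
  stable <- 0
  for (k in 1:10) {
    g <- random_glcm(8L)
    perm <- sample(8L)
    gp <- g; gp$p <- g$p[perm, perm]
    expect_equal(second_order_features(gp)["glcm_entropy"],
                 second_order_features(g)["glcm_entropy"],
                 tolerance = 1e-12)
    if (isTRUE(all.equal(second_order_features(gp)["glcm_contrast"],
                         second_order_features(g)["glcm_contrast"])))
      stable <- stable + 1
  }
  expect_lt(stable, 10)
})

test_that("features ignore voxels outside the mask", {
  ph <- generate_phantom(small_phantom_config(seed = 5L, mods = "suv"))
  cfg <- discretization_config()
  base_fo <- first_order_features(ph$images$suv, ph$mask, cfg)
  base_so <- second_order_features(compute_glcm(
    discretize(ph$images$suv, ph$mask, cfg)))
  fuzzed <- ph$images$suv$data
  set.seed(8)
  fuzzed[ph$mask$data == 0] <- rnorm(sum(ph$mask$data == 0), 100, 50)
  img2 <- volume_image(fuzzed, ph$images$suv$spacing, "suv")
  expect_identical(first_order_features(img2, ph$mask, cfg), base_fo)
  expect_identical(second_order_features(compute_glcm(
    discretize(img2, ph$mask, cfg))), base_so)
})

test_that("maximum diameter is exact on known masks and matches brute force", {
  single <- vol_with_values(1)
  expect_equal(max_diameter(single$mask), 0)
  # voxels at indices (0,0,0) and (0,0,3) with spacing (1,1,2): 6 mm
  m <- array(0, c(2L, 2L, 4L)); m[1, 1, 1] <- 1; m[1, 1, 4] <- 1
  expect_equal(max_diameter(seg_mask(m, c(1, 1, 2))), 6)
  # boundary-restricted computation equals all-pairs brute force
  set.seed(12)
  for (k in 1:5) {
    a <- array(as.numeric(runif(6 * 6 * 5) < 0.4), c(6L, 6L, 5L))
    if (sum(a) < 2) a[1:2] <- 1
    sp <- runif(3, 0.5, 3)
    msk <- seg_mask(a, sp)
    xyz <- sweep(which(a == 1, arr.ind = TRUE), 2, sp, `*`)
    expect_equal(max_diameter(msk), max(dist(xyz)))
  }
})

test_that("cohort extraction has the contracted shape and handles gaps", {
  coh <- small_cohort(n = 2L, seed = 6L)
  tab <- extract_cohort_features(coh)
  expect_identical(nrow(tab), 4L)
  expect_identical(ncol(tab), 2L + 5L * 24L + 3L)
  expect_identical(names(tab)[1:2], c("case_id", "metastatic"))
  expect_identical(tail(names(tab), 3),
                   c("suv_max", "adc_mean", "max_diameter_mm"))
  # consistency ties between comparators and feature cells
  expect_equal(tab$suv_max, tab$suv_fo_max)
  expect_equal(tab$adc_mean, tab$adc_fo_mean)
  # a case missing DWI gets NA in the 24 DWI columns only
  c1 <- coh$cases[[1]]
  no_dwi <- case_record(c1$case_id, c1$images[setdiff(names(c1$images),
                                                      "dwi")],
                        c1$mask, c1$metastatic)
  tab2 <- extract_cohort_features(cohort(list(no_dwi, coh$cases[[2]])))
  dwi_cols <- grep("^dwi_", names(tab2), value = TRUE)
  expect_true(all(is.na(tab2[1, dwi_cols])))
  expect_false(anyNA(tab2[2, dwi_cols]))
  expect_false(anyNA(tab2[1, grep("^suv_", names(tab2), value = TRUE)]))
  # determinism
  expect_identical(tab, extract_cohort_features(coh))
  # CSV round trip
  f <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(tab, f)
  expect_equal(as.data.frame(read_feature_table(f)), as.data.frame(tab),
               tolerance = 1e-12)
})
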