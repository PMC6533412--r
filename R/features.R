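# Whole-tumour feature engine: 12 first-order histogram features and 12
# second-order GLCM features per modality, plus SUV_max, ADC_mean and the
# maximum (Feret) diameter of the mask.
#
# Conventions fixed package-wide: fixed-bin-number discretization over the
# in-ROI range; 3-D GLCM at Chebyshev distance 1 over the 13 unique
# directions, symmetrized, counts merged across directions before
# normalization (per-direction feature averaging available); entropies in
# bits (log base 2) with 0*log0 = 0; population (N-denominator) moments and
# excess kurtosis; percentiles by linear interpolation between order
# statistics.

#' Names of the 12 first-order and 12 second-order features
#'
#' First-order (`fo_*`): mean, standard deviation, median, minimum, maximum,
#' 10th/90th percentile, histogram entropy, uniformity, excess kurtosis,
#' skewness, coefficient of variation. Second-order (`glcm_*`): entropy,
#' contrast, homogeneity (inverse difference moment), homogeneity
#' normalized, angular second moment, joint maximum, joint average, joint
#' variance, inverse difference, inverse difference normalized, correlation,
#' autocorrelation.
#'
#' @return character vector of 12 names.
#' @export
first_order_names <- function() {
  c("fo_mean", "fo_sd", "fo_median", "fo_min", "fo_max", "fo_p10", "fo_p90",
    "fo_entropy", "fo_uniformity", "fo_kurtosis", "fo_skewness", "fo_cov")
}

#' @rdname first_order_names
#' @export
second_order_names <- function() {
  c("glcm_entropy", "glcm_contrast", "glcm_homogeneity",
    "glcm_homogeneity_norm", "glcm_asm", "glcm_joint_max", "glcm_joint_avg",
    "glcm_joint_var", "glcm_inv_diff", "glcm_inv_diff_norm",
    "glcm_correlation", "glcm_autocorrelation")
}

#' Discretization configuration
#'
#' Fixed bin number over the in-ROI intensity range, the conventional
#' exploratory choice when absolute calibration differs across modalities:
#' bin `i` covers the i-th of `n_bins` equal-width bins spanning
#' `[min, max]` of the in-mask values; the maximum maps to level `n_bins`; a
#' constant ROI maps every voxel to level 1.
#'
#' @param n_bins number of grey levels (default 64).
#' @param glcm_distance voxel offset magnitude for the GLCM (default 1).
#' @param glcm_policy `"merged"` (sum direction counts, then normalize) or
#'   `"averaged"` (compute features per direction, then average).
#' @return An object of class `discretization_config`.
#' @export
discretization_config <- function(n_bins = 64L, glcm_distance = 1L,
                                  glcm_policy = c("merged", "averaged")) {
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("n_bins must be >= 2", call. = FALSE)
  structure(list(n_bins = n_bins, glcm_distance = as.integer(glcm_distance),
                 glcm_policy = match.arg(glcm_policy)),
            class = "discretization_config")
}

roi_values <- function(image, mask) {
  if (!same_grid(image, mask))
    stop("image and mask are on different grids", call. = FALSE)
  v <- image$data[mask$data == 1]
  if (!all(is.finite(v)))
    stop("non-finite value inside the mask", call. = FALSE)
  v
}

#' Discretize in-mask intensities to integer grey levels
#'
#' @param image a [volume_image].
#' @param mask a [seg_mask] on the same grid.
#' @param cfg a [discretization_config].
#' @param value_range optional length-2 numeric: fix the bin edges to this
#'   intensity range instead of the in-mask `[min, max]`; values outside it
#'   clamp to the end bins. Used by the perturbation study to freeze the
#'   original segmentation's edges when re-extracting under perturbed masks.
#' @return A list with `levels` (3-D integer array, `NA` outside the mask)
#'   and `n_levels`.
#' @export
discretize <- function(image, mask, cfg = discretization_config(),
                       value_range = NULL) {
  v <- roi_values(image, mask)
  ng <- cfg$n_bins
  rng <- if (is.null(value_range)) range(v) else sort(value_range)
  lev <- if (rng[2] > rng[1]) {
    pmax(1L, pmin(ng, floor((v - rng[1]) / (rng[2] - rng[1]) * ng) + 1L))
  } else {
    rep(1L, length(v))
  }
  out <- array(NA_integer_, dim(mask$data))
  out[mask$data == 1] <- as.integer(lev)
  list(levels = out, n_levels = ng)
}

pop_moments <- function(v) {
  m <- mean(v)
  s2 <- mean((v - m)^2)
  s <- sqrt(s2)
  skew <- if (s > 0) mean((v - m)^3) / s^3 else NA_real_
  kurt <- if (s > 0) mean((v - m)^4) / s2^2 - 3 else NA_real_
  list(mean = m, sd = s, skewness = skew, kurtosis = kurt)
}

#' First-order (histogram) features of a masked volume
#'
#' Moments use the raw in-mask values with population (N) denominators;
#' entropy (bits) and uniformity use the `n_bins`-level discretized
#' histogram. The coefficient of variation is `NA` when the mean is zero.
#'
#' @inheritParams discretize
#' @return Named numeric vector of the 12 [first_order_names()].
#' @export
first_order_features <- function(image, mask, cfg = discretization_config(),
                                 value_range = NULL) {
  v <- roi_values(image, mask)
  mo <- pop_moments(v)
  lev <- discretize(image, mask, cfg, value_range)
  p <- tabulate(lev$levels[!is.na(lev$levels)], nbins = lev$n_levels)
  p <- p / sum(p)
  pz <- p[p > 0]
  q <- stats::quantile(v, c(0.1, 0.5, 0.9), names = FALSE, type = 7)
  c(fo_mean = mo$mean, fo_sd = mo$sd, fo_median = q[2],
    fo_min = min(v), fo_max = max(v), fo_p10 = q[1], fo_p90 = q[3],
    fo_entropy = -sum(pz * log2(pz)), fo_uniformity = sum(p^2),
    fo_kurtosis = mo$kurtosis, fo_skewness = mo$skewness,
    fo_cov = if (mo$mean == 0) NA_real_ else mo$sd / mo$mean)
}

#' Grey-level co-occurrence matrix of a discretized ROI
#'
#' For each of the 13 unique 3-D directions at Chebyshev distance
#' `distance`, ordered level pairs whose both voxels lie inside the mask are
#' counted and symmetrized (counts plus their transpose). Under the default
#' `merged` policy the counts are summed over directions and normalized to a
#' single probability matrix; `per_direction = TRUE` returns the 13
#' direction-wise matrices and their pair counts instead.
#'
#' @param levels output of [discretize()].
#' @param distance voxel offset magnitude (default 1).
#' @param per_direction return per-direction matrices instead of merging.
#' @return An object of class `glcm_matrix` with fields `p` (Ng x Ng
#'   probabilities), `n_levels`, `distance`, `n_pairs`; or, with
#'   `per_direction = TRUE`, a list of such objects.
#' @export
compute_glcm <- function(levels, distance = 1L, per_direction = FALSE) {
  lev <- levels$levels
  ng <- levels$n_levels
  dirs <- glcm_directions()
  dm <- dim(lev)
  per <- vector("list", nrow(dirs))
  for (k in seq_len(nrow(dirs))) {
    d <- dirs[k, ] * distance
    idx_a <- idx_b <- vector("list", 3L)
    ok <- TRUE
    for (ax in 1:3) {
      o <- d[ax]
      if (abs(o) >= dm[ax]) { ok <- FALSE; break }
      if (o >= 0) {
        idx_a[[ax]] <- 1:(dm[ax] - o); idx_b[[ax]] <- (1 + o):dm[ax]
      } else {
        idx_a[[ax]] <- (1 - o):dm[ax]; idx_b[[ax]] <- 1:(dm[ax] + o)
      }
    }
    counts <- matrix(0, ng, ng)
    if (ok) {
      la <- lev[idx_a[[1]], idx_a[[2]], idx_a[[3]]]
      lb <- lev[idx_b[[1]], idx_b[[2]], idx_b[[3]]]
      valid <- !is.na(la) & !is.na(lb)
      if (any(valid)) {
        tab <- tabulate(la[valid] + ng * (lb[valid] - 1L), nbins = ng * ng)
        m <- matrix(tab, ng, ng)
        counts <- m + t(m)
      }
    }
    per[[k]] <- counts
  }
  total <- Reduce(`+`, per)
  if (sum(total) == 0)
    stop("degenerate GLCM: no in-mask voxel pairs at this distance",
         call. = FALSE)
  make_one <- function(counts) {
    structure(list(p = counts / sum(counts), n_levels = ng,
                   distance = as.integer(distance), n_pairs = sum(counts)),
              class = "glcm_matrix")
  }
  if (per_direction) {
    per <- per[vapply(per, sum, 0) > 0]
    lapply(per, make_one)
  } else {
    make_one(total)
  }
}

#' Second-order (GLCM) texture features
#'
#' All sums run over matrix cells with row level `i` and column level `j`;
#' `p` is the normalized symmetric co-occurrence matrix. Entropy is in bits.
#' Correlation is the standard GLCM correlation, defined as 0 when the
#' marginal standard deviation vanishes (e.g. a constant ROI).
#'
#' @param glcm a `glcm_matrix` from [compute_glcm()].
#' @return Named numeric vector of the 12 [second_order_names()].
#' @export
second_order_features <- function(glcm) {
  stopifnot(inherits(glcm, "glcm_matrix"))
  p <- glcm$p
  ng <- glcm$n_levels
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  dij <- i - j
  pz <- p[p > 0]
  mu <- sum(i * p)                     # joint average (= marginal mean: p symmetric)
  px <- rowSums(p)
  sig2 <- sum((seq_len(ng) - mu)^2 * px)
  corr <- if (sig2 > 0) (sum(i * j * p) - mu^2) / sig2 else 0
  c(glcm_entropy = -sum(pz * log2(pz)),
    glcm_contrast = sum(dij^2 * p),
    glcm_homogeneity = sum(p / (1 + dij^2)),
    glcm_homogeneity_norm = sum(p / (1 + (dij / ng)^2)),
    glcm_asm = sum(p^2),
    glcm_joint_max = max(p),
    glcm_joint_avg = mu,
    glcm_joint_var = sum((i - mu)^2 * p),
    glcm_inv_diff = sum(p / (1 + abs(dij))),
    glcm_inv_diff_norm = sum(p / (1 + abs(dij) / ng)),
    glcm_correlation = corr,
    glcm_autocorrelation = sum(i * j * p))
}

texture_features <- function(image, mask, cfg = discretization_config(),
                             value_range = NULL) {
  lev <- discretize(image, mask, cfg, value_range)
  if (cfg$glcm_policy == "merged") {
    second_order_features(compute_glcm(lev, cfg$glcm_distance))
  } else {
    per <- compute_glcm(lev, cfg$glcm_distance, per_direction = TRUE)
    feats <- vapply(per, second_order_features,
                    numeric(length(second_order_names())))
    rowMeans(feats)
  }
}

boundary_voxels <- function(mask_arr) {
  offs <- neighbourhood_offsets(26L)
  interior <- array(TRUE, dim(mask_arr))
  for (k in seq_len(nrow(offs)))
    interior <- interior & (shift_array(mask_arr, offs[k, ]) == 1)
  which(mask_arr == 1 & !interior, arr.ind = TRUE)
}

#' Maximum (Feret) diameter of a mask, in mm
#'
#' Largest Euclidean distance between centres of any two foreground voxels.
#' Restricting the pair search to boundary voxels (foreground voxels with at
#' least one non-foreground 26-neighbour, grid edges counting as outside) is
#' exact: an all-pairs maximum is always attained on the boundary. A
#' single-voxel mask has diameter 0.
#'
#' @param mask a [seg_mask].
#' @return Diameter in mm.
#' @export
max_diameter <- function(mask) {
  stopifnot(inherits(mask, "seg_mask"))
  bv <- boundary_voxels(mask$data)
  if (nrow(bv) < 2L) return(0)
  xyz <- sweep(bv, 2L, mask$spacing, `*`)
  max(stats::dist(xyz))
}

#' Extract the full feature table for a cohort
#'
#' One row per case with columns `case_id`, `metastatic`, then for each
#' modality in [GOJRAD_MODALITIES] the 12 first-order and 12 second-order
#' features (named `<modality>_<feature>`), then the three clinical
#' comparators `suv_max` (the SUV first-order maximum), `adc_mean` (the ADC
#' first-order mean) and `max_diameter_mm`. Cells for missing modalities are
#' `NA`; a per-case feature failure is recorded as `NA` with a warning, not
#' an error.
#'
#' @param x a [cohort].
#' @param cfg a [discretization_config].
#' @return A `data.frame` (class `feature_table`).
#' @export
extract_cohort_features <- function(x, cfg = discretization_config()) {
  stopifnot(inherits(x, "cohort"))
  feat_names <- c(first_order_names(), second_order_names())
  cols <- as.vector(t(outer(GOJRAD_MODALITIES, feat_names, paste, sep = "_")))
  rows <- lapply(x$cases, function(cs) {
    row <- stats::setNames(rep(NA_real_, length(cols)), cols)
    for (m in GOJRAD_MODALITIES) {
      img <- cs$images[[m]]
      if (is.null(img)) next
      vals <- tryCatch(
        c(first_order_features(img, cs$mask, cfg),
          texture_features(img, cs$mask, cfg)),
        error = function(e) {
          warning(sprintf("case %s, modality %s: %s", cs$case_id, m,
                          conditionMessage(e)), call. = FALSE)
          NULL
        })
      if (!is.null(vals)) row[paste(m, names(vals), sep = "_")] <- vals
    }
    data.frame(case_id = cs$case_id, metastatic = cs$metastatic,
               as.list(row), suv_max = unname(row["suv_fo_max"]),
               adc_mean = unname(row["adc_fo_mean"]),
               max_diameter_mm = max_diameter(cs$mask),
               check.names = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("feature_table", "data.frame")
  out
}

#' Write / read a feature table as CSV
#'
#' @param x a `feature_table`.
#' @param path CSV path.
#' @return `path` (write) or the re-read `feature_table` (read), invisibly
#'   for the writer.
#' @export
write_feature_table <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  out <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  out$metastatic <- as.logical(out$metastatic)
  class(out) <- c("feature_table", "data.frame")
  out
}
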