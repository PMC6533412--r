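# Segmentation-perturbation robustness: dilate/erode each tumour mask by one
# voxel, re-extract every feature, and summarise volume change, relative
# feature error and the intraclass correlation coefficient ICC(2,1) between
# original and perturbed values.

#' Morphologically perturb a mask by one voxel
#'
#' One iteration of 3-D dilation or erosion with a 26-connected 3x3x3
#' structuring element (6-connected cross available). Dilation is a superset
#' of the original, erosion a subset; an erosion that removes every
#' foreground voxel is an error.
#'
#' @param mask a [seg_mask].
#' @param mode `"dilate"` or `"erode"`.
#' @param connectivity 26 (default) or 6.
#' @return The perturbed [seg_mask].
#' @export
perturb_mask <- function(mask, mode = c("dilate", "erode"),
                         connectivity = 26L) {
  stopifnot(inherits(mask, "seg_mask"))
  mode <- match.arg(mode)
  offs <- neighbourhood_offsets(connectivity)
  a <- mask$data
  out <- a
  for (k in seq_len(nrow(offs))) {
    s <- shift_array(a, offs[k, ])
    out <- if (mode == "dilate") pmax(out, s) else pmin(out, s)
  }
  if (sum(out) < 1)
    stop("degenerate erosion: mask vanished", call. = FALSE)
  seg_mask(out, mask$spacing)
}

#' Percent volume change between two masks
#'
#' `|V_perturbed - V_original| / V_original * 100`, with volume = foreground
#' voxel count times voxel volume (the spacing cancels on a shared grid).
#'
#' @param original,perturbed [seg_mask]s on the same grid.
#' @return Percent change (>= 0).
#' @export
volume_change_pct <- function(original, perturbed) {
  stopifnot(inherits(original, "seg_mask"), inherits(perturbed, "seg_mask"))
  if (!same_grid(original, perturbed))
    stop("masks are on different grids", call. = FALSE)
  v0 <- sum(original$data)
  100 * abs(sum(perturbed$data) - v0) / v0
}

#' Percent feature reproducibility error
#'
#' `|f_perturbed - f_original| / |f_original| * 100`; `NA` (excluded from
#' aggregation) when the original value's magnitude is at most `eps`.
#'
#' @param f_orig,f_pert numeric feature values (vectorized).
#' @param eps near-zero baseline guard (default 1e-8).
#' @return Percent error, `NA` where undefined.
#' @export
feature_error_pct <- function(f_orig, f_pert, eps = 1e-8) {
  out <- 100 * abs(f_pert - f_orig) / abs(f_orig)
  out[!is.finite(f_orig) | !is.finite(f_pert) | abs(f_orig) <= eps] <- NA_real_
  out
}

#' ICC(2,1): two-way random effects, absolute agreement, single measurement
#'
#' The original and perturbed feature values are treated as two raters over
#' cases. Computed from the two-way ANOVA mean squares
#' `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)` with k = 2;
#' absolute agreement, so a systematic offset between the two measurements
#' lowers the ICC. `NA` when the between-case variance is zero.
#'
#' @param original,perturbed paired numeric vectors, length >= 3, complete.
#' @return ICC in `[-1, 1]`, or `NA` when undefined.
#' @export
icc_absolute_agreement <- function(original, perturbed) {
  x <- cbind(original, perturbed)
  stopifnot(nrow(x) >= 3L)
  if (anyNA(x)) stop("paired values must be complete", call. = FALSE)
  n <- nrow(x); k <- 2
  grand <- mean(x)
  row_m <- rowMeans(x); col_m <- colMeans(x)
  sst <- sum((x - grand)^2)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  if (msr <= .Machine$double.eps * max(1, abs(grand))^2 || denom <= 0)
    return(NA_real_)
  (msr - mse) / denom
}

#' Run the full segmentation-perturbation study
#'
#' For each case the mask is dilated and eroded by one voxel and every
#' first- and second-order feature is re-extracted under the perturbed
#' masks, with discretization bin edges frozen from the original ROI so the
#' comparison isolates segmentation geometry rather than bin-width
#' re-estimation. Cases whose erosion removes the whole tumour are excluded
#' from the erosion arm with a warning. Volume change is a property of the shared
#' per-case mask, so it is summarised per mode over cases; feature error is
#' summarised per modality and mode over cases x features; the ICC against
#' the original values is reported per (mode, modality, feature).
#'
#' @param x a [cohort].
#' @param cfg a [discretization_config].
#' @param connectivity structuring element connectivity (26 or 6).
#' @param eps near-zero baseline guard for [feature_error_pct()].
#' @return An object of class `perturbation_report`: list with
#'   `volume_change` (data.frame: mode, mean_pct, sd_pct, n_cases),
#'   `feature_error` (data.frame: mode, modality, mean_err_pct, sd_err_pct,
#'   n_values) and `icc` (data.frame: mode, modality, feature, icc,
#'   mean_err_pct, sd_err_pct).
#' @export
run_perturbation_study <- function(x, cfg = discretization_config(),
                                   connectivity = 26L, eps = 1e-8) {
  stopifnot(inherits(x, "cohort"))
  base_tab <- extract_cohort_features(x, cfg)
  feat_cols <- modality_feature_columns(base_tab)
  modes <- c("dilate", "erode")
  vol_rows <- list(); err_rows <- list(); icc_rows <- list()
  pert_tabs <- list()
  for (mode in modes) {
    kept <- logical(length(x$cases))
    pert_cases <- vector("list", length(x$cases))
    vols <- rep(NA_real_, length(x$cases))
    for (i in seq_along(x$cases)) {
      cs <- x$cases[[i]]
      pm <- tryCatch(perturb_mask(cs$mask, mode, connectivity),
                     error = function(e) {
                       warning(sprintf("case %s excluded from %s arm: %s",
                                       cs$case_id, mode,
                                       conditionMessage(e)), call. = FALSE)
                       NULL
                     })
      if (is.null(pm)) next
      kept[i] <- TRUE
      vols[i] <- volume_change_pct(cs$mask, pm)
      pert_cases[[i]] <- case_record(cs$case_id, cs$images, pm, cs$metastatic)
    }
    if (!any(kept)) next
    # features under the perturbed mask, with the discretization bin edges
    # frozen from the original ROI: otherwise re-estimated [min, max] edges
    # contract under erosion and the re-binning, not the geometry, dominates
    # entropy-family differences
    pert_rows <- lapply(which(kept), function(i) {
      cs <- x$cases[[i]]
      pm <- pert_cases[[i]]$mask
      row <- stats::setNames(rep(NA_real_, length(feat_cols)), feat_cols)
      for (m in GOJRAD_MODALITIES) {
        img <- cs$images[[m]]
        if (is.null(img)) next
        rng <- range(img$data[cs$mask$data == 1])
        vals <- tryCatch(
          c(first_order_features(img, pm, cfg, value_range = rng),
            texture_features(img, pm, cfg, value_range = rng)),
          error = function(e) {
            warning(sprintf("case %s, modality %s (%s arm): %s", cs$case_id,
                            m, mode, conditionMessage(e)), call. = FALSE)
            NULL
          })
        if (!is.null(vals)) row[paste(m, names(vals), sep = "_")] <- vals
      }
      as.data.frame(as.list(row), check.names = FALSE)
    })
    pert_tab <- do.call(rbind, pert_rows)
    pert_tabs[[mode]] <- list(kept = kept, table = pert_tab)
    vol_rows[[mode]] <- data.frame(
      mode = mode, mean_pct = mean(vols[kept]),
      sd_pct = stats::sd(vols[kept]), n_cases = sum(kept))
    for (m in GOJRAD_MODALITIES) {
      m_cols <- grep(paste0("^", m, "_"), feat_cols, value = TRUE)
      errs_all <- c()
      for (cn in m_cols) {
        f0 <- base_tab[[cn]][kept]
        f1 <- pert_tab[[cn]]
        if (all(is.na(f0)) || all(is.na(f1))) next
        errs <- feature_error_pct(f0, f1, eps)
        errs_all <- c(errs_all, errs[!is.na(errs)])
        icc <- if (sum(stats::complete.cases(f0, f1)) >= 3L)
          icc_absolute_agreement(f0[stats::complete.cases(f0, f1)],
                                 f1[stats::complete.cases(f0, f1)])
        else NA_real_
        icc_rows[[length(icc_rows) + 1L]] <- data.frame(
          mode = mode, modality = m,
          feature = sub(paste0("^", m, "_"), "", cn), icc = icc,
          mean_err_pct = mean(errs, na.rm = TRUE),
          sd_err_pct = stats::sd(errs[!is.na(errs)]))
      }
      if (length(errs_all))
        err_rows[[paste(mode, m)]] <- data.frame(
          mode = mode, modality = m, mean_err_pct = mean(errs_all),
          sd_err_pct = stats::sd(errs_all), n_values = length(errs_all))
    }
  }
  structure(list(volume_change = do.call(rbind, unname(vol_rows)),
                 feature_error = do.call(rbind, unname(err_rows)),
                 icc = do.call(rbind, icc_rows)),
            class = "perturbation_report")
}

#' Write a perturbation report's per-feature table to CSV
#'
#' Columns: mode, modality, feature, icc, mean_err_pct, sd_err_pct.
#'
#' @param x a `perturbation_report`.
#' @param path CSV path.
#' @export
write_perturbation_report <- function(x, path) {
  utils::write.csv(x$icc, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.perturbation_report <- function(x, ...) {
  cat("<perturbation_report>\n")
  cat("volume change (%):\n"); print(x$volume_change)
  cat("feature error (%) by modality:\n"); print(x$feature_error)
  invisible(x)
}
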