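# Core imaging data model: a modality-tagged scalar volume, a binary tumour
# mask on the same grid, one patient's record, and the labelled cohort.

#' Recognized imaging modalities
#'
#' Lower-case codes for the five modalities handled by the pipeline:
#' PET standardized uptake value (`suv`, unitless), T1-weighted (`t1w`) and
#' T2-weighted (`t2w`) MRI (arbitrary intensity), high-b diffusion-weighted
#' imaging (`dwi`, b = 900 s/mm^2), and the apparent diffusion coefficient
#' map (`adc`, conventionally 10^-3 mm^2/s).
#'
#' @export
GOJRAD_MODALITIES <- c("suv", "t1w", "t2w", "dwi", "adc")

#' Construct a modality-tagged 3-D volume
#'
#' @param data 3-D numeric array of voxel values; all values must be finite.
#' @param spacing numeric length-3 voxel size in mm per axis; strictly
#'   positive.
#' @param modality one of [GOJRAD_MODALITIES].
#' @return An object of class `volume_image`.
#' @export
volume_image <- function(data, spacing, modality) {
  data <- as.array(data)
  if (length(dim(data)) != 3L || any(dim(data) < 1L))
    stop("volume data must be a 3-D array with at least 1 voxel per axis",
         call. = FALSE)
  if (!all(is.finite(data)))
    stop("volume contains non-finite values", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 strictly positive values (mm)", call. = FALSE)
  modality <- match.arg(tolower(modality), GOJRAD_MODALITIES)
  structure(list(data = data, spacing = spacing, modality = modality),
            class = "volume_image")
}

#' Construct a binary segmentation mask
#'
#' Any non-zero stored value is treated as foreground and coerced to 1 (masks
#' exported as 0/255 are common); a warning is raised when coercion happens.
#'
#' @param data 3-D array; non-zero entries are foreground.
#' @param spacing numeric length-3 voxel size in mm per axis.
#' @return An object of class `seg_mask` whose `data` is a 0/1 array.
#' @export
seg_mask <- function(data, spacing) {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("mask data must be a 3-D array", call. = FALSE)
  if (!all(is.finite(data)))
    stop("mask contains non-finite values", call. = FALSE)
  if (any(data != 0 & data != 1)) {
    warning("mask values outside {0,1} coerced to binary foreground",
            call. = FALSE)
    data <- (data != 0) * 1
  }
  if (sum(data) < 1)
    stop("degenerate mask: no foreground voxel", call. = FALSE)
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 strictly positive values (mm)", call. = FALSE)
  structure(list(data = data, spacing = spacing), class = "seg_mask")
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    all(abs(a$spacing - b$spacing) < tol)
}

#' Construct one patient's record
#'
#' Bundles the available modality volumes, the tumour mask and the metastasis
#' label. Every image must share the mask's grid (shape and spacing); absent
#' modalities are simply not present in `images` and downstream feature
#' extraction records them as missing.
#'
#' @param case_id character scalar, unique within a cohort.
#' @param images named list of [volume_image]s, names drawn from
#'   [GOJRAD_MODALITIES].
#' @param mask a [seg_mask] on the same grid as every image.
#' @param metastatic logical; `TRUE` for M1, `FALSE` for M0, `NA` if
#'   unlabelled.
#' @return An object of class `case_record`.
#' @export
case_record <- function(case_id, images, mask, metastatic = NA) {
  stopifnot(is.character(case_id), length(case_id) == 1L, nzchar(case_id))
  if (!inherits(mask, "seg_mask")) stop("mask must be a seg_mask", call. = FALSE)
  if (length(images) == 0L)
    stop("a case needs at least one modality image", call. = FALSE)
  if (is.null(names(images)) || any(!names(images) %in% GOJRAD_MODALITIES) ||
      anyDuplicated(names(images)))
    stop("images must be uniquely named by modality", call. = FALSE)
  for (m in names(images)) {
    img <- images[[m]]
    if (!inherits(img, "volume_image"))
      stop("images must be volume_image objects", call. = FALSE)
    if (img$modality != m)
      stop(sprintf("image stored under '%s' is tagged '%s'", m, img$modality),
           call. = FALSE)
    if (!same_grid(img, mask))
      stop(sprintf("grid mismatch between %s image and mask for case %s",
                   m, case_id), call. = FALSE)
  }
  structure(list(case_id = case_id, images = images, mask = mask,
                 metastatic = as.logical(metastatic)),
            class = "case_record")
}

#' Construct a cohort from case records
#'
#' @param cases possibly empty list of [case_record]s with unique
#'   `case_id`s; manifest order is preserved. Fitting operations require at
#'   least two cases per class; emptiness is only legal for I/O.
#' @return An object of class `cohort` (a list with element `cases`).
#' @export
cohort <- function(cases = list()) {
  if (!all(vapply(cases, inherits, TRUE, "case_record")))
    stop("cases must be a list of case_record objects", call. = FALSE)
  ids <- vapply(cases, `[[`, "", "case_id")
  if (anyDuplicated(ids))
    stop("duplicate case_id in cohort: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  structure(list(cases = cases), class = "cohort")
}

#' @export
length.cohort <- function(x) length(x$cases)

#' Metastasis labels of a cohort
#'
#' @param x a [cohort].
#' @return logical vector, one element per case, in cohort order.
#' @export
cohort_labels <- function(x) {
  stopifnot(inherits(x, "cohort"))
  vapply(x$cases, `[[`, NA, "metastatic")
}

#' @export
print.volume_image <- function(x, ...) {
  cat(sprintf("<volume_image> %s  %s voxels  spacing %s mm\n",
              x$modality, paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 4), collapse = "x")))
  invisible(x)
}

#' @export
print.seg_mask <- function(x, ...) {
  cat(sprintf("<seg_mask> %s voxels, %d foreground\n",
              paste(dim(x$data), collapse = "x"), sum(x$data)))
  invisible(x)
}

#' @export
print.case_record <- function(x, ...) {
  cat(sprintf("<case_record> %s  modalities: %s  metastatic: %s\n",
              x$case_id, paste(names(x$images), collapse = ","),
              x$metastatic))
  invisible(x)
}

#' @export
print.cohort <- function(x, ...) {
  lab <- cohort_labels(x)
  cat(sprintf("<cohort> %d cases (%d metastatic, %d non-metastatic, %d unlabelled)\n",
              length(x$cases), sum(lab, na.rm = TRUE),
              sum(!lab, na.rm = TRUE), sum(is.na(lab))))
  invisible(x)
}
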