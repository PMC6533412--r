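# NIfTI / CSV manifest input-output. Images and masks are NIfTI volumes on a
# shared per-case grid; the cohort manifest is a CSV with one row per case
# and one path column per modality plus the mask, paths relative to the
# manifest's directory.

read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))   # drop NIfTI header attributes
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  if (length(dim(arr)) != 3L)
    stop(sprintf("%s: expected a 3-D volume, got %d dims",
                 path, length(dim(arr))), call. = FALSE)
  sp <- RNifti::pixdim(img)
  if (length(sp) < 3L) sp <- c(sp, rep(1, 3L - length(sp)))
  list(data = arr, spacing = as.numeric(sp[1:3]))
}

write_nifti_volume <- function(data, spacing, path) {
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read one case from NIfTI files
#'
#' Loads the mask and every listed modality image, validates that all share
#' the mask's grid (shape and voxel spacing), and returns an unlabelled
#' [case_record]. Modalities absent from `image_paths` are recorded as
#' missing; feature extraction later marks their columns as `NA` rather than
#' failing at load time.
#'
#' @param image_paths named character vector or list, names drawn from
#'   [GOJRAD_MODALITIES], values NIfTI paths (`.nii` / `.nii.gz`).
#' @param mask_path NIfTI path of the binary tumour mask.
#' @param case_id identifier for the record (defaults to the mask filename).
#' @param metastatic optional logical label.
#' @return A [case_record].
#' @export
read_case <- function(image_paths, mask_path, case_id = NULL,
                      metastatic = NA) {
  image_paths <- as.list(image_paths)
  image_paths <- image_paths[!vapply(image_paths, function(p)
    is.null(p) || is.na(p) || !nzchar(p), TRUE)]
  if (!file.exists(mask_path))
    stop("mask file not found: ", mask_path, call. = FALSE)
  for (p in image_paths)
    if (!file.exists(p)) stop("image file not found: ", p, call. = FALSE)
  m <- read_nifti_volume(mask_path)
  mask <- seg_mask(m$data, m$spacing)
  images <- list()
  for (mod in names(image_paths)) {
    v <- read_nifti_volume(image_paths[[mod]])
    images[[mod]] <- volume_image(v$data, v$spacing, mod)
  }
  case_id <- case_id %||% sub("\\.nii(\\.gz)?$", "", basename(mask_path))
  case_record(case_id, images, mask, metastatic)
}

#' Read a cohort manifest
#'
#' The manifest is a CSV with columns `case_id`, `metastatic` (0/1) and
#' `mask`, plus optional per-modality path columns (`suv`, `t1w`, `t2w`,
#' `dwi`, `adc`). Blank path cells mean the modality is missing for that
#' case. All paths are resolved relative to the manifest's directory; row
#' order is preserved.
#'
#' @param path manifest CSV path.
#' @return A labelled [cohort].
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  need <- c("case_id", "metastatic", "mask")
  if (!all(need %in% names(df)))
    stop("manifest must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (nrow(df) == 0L) stop("manifest has no cases", call. = FALSE)
  if (anyDuplicated(df$case_id))
    stop("duplicate case_id in manifest: ",
         paste(unique(df$case_id[duplicated(df$case_id)]), collapse = ", "),
         call. = FALSE)
  lab <- df$metastatic
  if (!all(lab %in% c("0", "1")))
    stop("metastatic label must be 0 or 1", call. = FALSE)
  root <- dirname(normalizePath(path))
  mods <- intersect(GOJRAD_MODALITIES, names(df))
  cases <- lapply(seq_len(nrow(df)), function(i) {
    paths <- list()
    for (m in mods) {
      p <- df[[m]][i]
      if (!is.na(p) && nzchar(p)) paths[[m]] <- file.path(root, p)
    }
    read_case(paths, file.path(root, df$mask[i]),
              case_id = df$case_id[i], metastatic = lab[i] == "1")
  })
  cohort(cases)
}
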