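# Synthetic multi-modal tumour phantoms. Each modality is a stationary
# Gaussian random field with a tunable correlation length: seeded white noise
# is convolved with an isotropic Gaussian kernel of standard deviation ell
# (mm), rescaled to unit variance inside the tumour mask, scaled by an
# amplitude, shifted by a modality mean, and overlaid with independent
# voxel noise. Longer ell means locally smoother texture, hence a lower GLCM
# entropy; that single knob is what plants (or withholds) the class effect in
# generated cohorts.

#' Phantom configuration
#'
#' @param grid_shape integer length-3 voxels per axis.
#' @param spacing numeric length-3 voxel size in mm.
#' @param semi_axes numeric length-3 ellipsoid tumour semi-axes in mm; the
#'   ellipsoid (centred in the grid) must fit inside the grid.
#' @param modalities named list (names in [GOJRAD_MODALITIES]); each element
#'   a list with `mean`, `amplitude` (>= 0), `corr_length_mm` (>= 0, Gaussian
#'   kernel SD of the texture field) and `noise_sd` (>= 0, independent
#'   voxelwise noise). Optionally `rough_length_mm` (>= 0) switches on the
#'   two-scale construction: the field combines a smooth component at
#'   `corr_length_mm` and a rough one at `rough_length_mm`, zonally when
#'   `zonal = TRUE` (patches set by a modulator field of scale
#'   `zone_length_mm`, default 12 mm) or pointwise otherwise; the two
#'   variants share their autocovariance but differ in co-occurrence
#'   entropy.
#' @param seed integer RNG seed; phantoms are deterministic given the seed.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(grid_shape = c(32L, 32L, 24L),
                           spacing = c(2, 2, 2),
                           semi_axes = c(18, 14, 20),
                           modalities = default_modality_params(),
                           seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 1L),
            length(spacing) == 3L, all(spacing > 0),
            length(semi_axes) == 3L, all(semi_axes > 0),
            length(seed) == 1L, is.finite(seed))
  half_extent <- (grid_shape - 1) * spacing / 2
  if (any(semi_axes > half_extent))
    stop("ellipsoid exceeds grid: semi-axes must fit within ",
         paste(signif(half_extent, 4), collapse = "x"), " mm", call. = FALSE)
  if (is.null(names(modalities)) ||
      !all(names(modalities) %in% GOJRAD_MODALITIES))
    stop("modalities must be named by modality code", call. = FALSE)
  for (m in names(modalities)) {
    p <- modalities[[m]]
    stopifnot(all(c("mean", "amplitude", "corr_length_mm", "noise_sd")
                  %in% names(p)))
    if (p$amplitude < 0 || p$corr_length_mm < 0 || p$noise_sd < 0)
      stop("amplitude, corr_length_mm and noise_sd must be >= 0",
           call. = FALSE)
    if (!is.null(p$rough_length_mm) && p$rough_length_mm < 0)
      stop("rough_length_mm must be >= 0", call. = FALSE)
  }
  structure(list(grid_shape = grid_shape, spacing = as.numeric(spacing),
                 semi_axes = as.numeric(semi_axes),
                 modalities = modalities, seed = as.integer(seed)),
            class = "phantom_config")
}

#' Default per-modality texture parameters
#'
#' Means and amplitudes sit in plausible clinical ranges (SUV around 8 for an
#' FDG-avid tumour, ADC around 1.5 x 10^-3 mm^2/s, arbitrary units for the
#' MRI intensities); every modality defaults to a 3 mm correlation length and
#' modest voxel noise.
#'
#' @return named list usable as the `modalities` field of [phantom_config()].
#' @export
default_modality_params <- function() {
  list(
    suv = list(mean = 8,    amplitude = 2,   corr_length_mm = 3, noise_sd = 0.3),
    t1w = list(mean = 300,  amplitude = 60,  corr_length_mm = 3, noise_sd = 10),
    t2w = list(mean = 120,  amplitude = 30,  corr_length_mm = 3, noise_sd = 5),
    dwi = list(mean = 200,  amplitude = 50,  corr_length_mm = 3, noise_sd = 8),
    adc = list(mean = 1.5,  amplitude = 0.4, corr_length_mm = 3, noise_sd = 0.05)
  )
}

standardize_in <- function(f, inside) {
  mu <- mean(f[inside]); s <- stats::sd(f[inside])
  if (is.finite(s) && s > 0) (f - mu) / s else f * 0
}

# One modality's unit-variance texture field. Plain single-scale mode:
# Gaussian-smoothed white noise at correlation length `corr_length_mm`.
# Two-scale mode (when `rough_length_mm` is set): two independent component
# fields, a smooth one S at `corr_length_mm` and a rough one R at
# `rough_length_mm`, are combined per the `mixing` rule:
#   "sum"         (R + S)/sqrt(2): jointly Gaussian, homoscedastic.
#   "zonal"       R occupies the half of the tumour where an independent
#                 very smooth modulator field (scale `zone_length_mm`) is
#                 above its in-mask median, S the other half; local
#                 roughness varies spatially but independently of the local
#                 grey level.
#   "zonal_level" as "zonal" but the rough half is the superlevel set of S
#                 itself, so local roughness is coupled to the grey level.
#   "level_mod"   the rough component is added, with gain `rough_gain`, on
#                 the superlevel half of S (roughness grows with the level).
#   "zone_mod"    as "level_mod" but gated by the independent modulator.
# The zonal variants are half/half mixtures of R- and S-type local
# differences sharing their autocovariance with "sum", which makes them
# useful for studying how strongly the second-order features co-move (see
# the methods vignette). Finally a normal-scores transform pins the in-mask
# marginal to exact N(0,1) quantiles so first-order features carry no
# texture signal.
simulate_texture_field <- function(p, gs, spacing, inside) {
  n <- prod(gs)
  if (is.null(p$rough_length_mm)) {
    f <- gaussian_smooth(array(stats::rnorm(n), gs),
                         p$corr_length_mm / spacing)
    f <- standardize_in(f, inside)
  } else {
    mixing <- p$mixing %||% "sum"
    smoothf <- standardize_in(
      gaussian_smooth(array(stats::rnorm(n), gs), p$corr_length_mm / spacing),
      inside)
    roughf <- standardize_in(
      gaussian_smooth(array(stats::rnorm(n), gs), p$rough_length_mm / spacing),
      inside)
    zone <- gaussian_smooth(array(stats::rnorm(n), gs),
                            (p$zone_length_mm %||% 12) / spacing)
    gain <- p$rough_gain %||% 1.2
    f <- switch(mixing,
      sum = (roughf + smoothf) / sqrt(2),
      zonal = {
        w <- (zone > stats::median(zone[inside])) * 1
        w * roughf + (1 - w) * smoothf
      },
      zonal_level = {
        w <- (smoothf > stats::median(smoothf[inside])) * 1
        w * roughf + (1 - w) * smoothf
      },
      level_mod = {
        w <- (smoothf > stats::median(smoothf[inside])) * 1
        smoothf + gain * w * roughf
      },
      zone_mod = {
        w <- (zone > stats::median(zone[inside])) * 1
        smoothf + gain * w * roughf
      },
      stop("mixing must be one of sum, zonal, zonal_level, level_mod, zone_mod",
           call. = FALSE))
    f <- standardize_in(f, inside)
  }
  n_in <- sum(inside)
  if (stats::sd(f[inside]) > 0 && n_in > 1L)
    f[inside] <- stats::qnorm((rank(f[inside], ties.method = "first") -
                                 0.5) / n_in)
  f
}

ellipsoid_mask <- function(grid_shape, spacing, semi_axes) {
  centre <- (grid_shape + 1) / 2
  ax <- lapply(1:3, function(k) ((seq_len(grid_shape[k]) - centre[k]) *
                                   spacing[k] / semi_axes[k])^2)
  r2 <- outer(outer(ax[[1]], ax[[2]], `+`), ax[[3]], `+`)
  (r2 <= 1) * 1
}

#' Generate one multi-modal tumour phantom
#'
#' The mask is the ellipsoid indicator; each configured modality is
#' `mean + amplitude * field + noise` where `field` is a Gaussian-smoothed
#' white-noise field standardized to zero mean / unit variance inside the
#' mask, and `noise` is independent N(0, noise_sd^2). Deterministic given
#' `config$seed`; each modality draws from its own derived sub-seed, so
#' adding or removing a modality does not disturb the others' fields.
#'
#' @param config a [phantom_config].
#' @return An unlabelled [case_record] with `case_id = "phantom"`.
#' @export
generate_phantom <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  gs <- config$grid_shape
  n <- prod(gs)
  mask_arr <- ellipsoid_mask(gs, config$spacing, config$semi_axes)
  inside <- mask_arr == 1
  set.seed(config$seed)
  modality_seeds <- stats::setNames(
    sample.int(.Machine$integer.max - 1L, length(GOJRAD_MODALITIES)),
    GOJRAD_MODALITIES)
  images <- list()
  for (mod in intersect(GOJRAD_MODALITIES, names(config$modalities))) {
    p <- config$modalities[[mod]]
    set.seed(modality_seeds[[mod]])
    f <- simulate_texture_field(p, gs, config$spacing, inside)
    noise <- array(stats::rnorm(n), gs)
    img <- p$mean + p$amplitude * f + p$noise_sd * noise
    images[[mod]] <- volume_image(img, config$spacing, mod)
  }
  case_record("phantom", images, seg_mask(mask_arr, config$spacing))
}

#' Cohort configuration
#'
#' @param n_metastatic,n_nonmetastatic class sizes.
#' @param template_metastatic,template_nonmetastatic per-class
#'   [phantom_config] templates.
#' @param jitter fractional per-case variation in `[0, 1)`: each case's
#'   texture parameters and tumour semi-axes are the template values times
#'   independent Uniform(1 - jitter, 1 + jitter) factors.
#' @param seed global seed; case `i` draws from a stream seeded with
#'   `seed + i`, so a cohort is reproducible case by case and stable under
#'   appending cases at the end.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_metastatic = 10L, n_nonmetastatic = 10L,
                          template_metastatic = phantom_config(),
                          template_nonmetastatic = phantom_config(),
                          jitter = 0.15, seed = 1L) {
  stopifnot(n_metastatic >= 0L, n_nonmetastatic >= 0L,
            jitter >= 0, jitter < 1,
            inherits(template_metastatic, "phantom_config"),
            inherits(template_nonmetastatic, "phantom_config"))
  structure(list(n_metastatic = as.integer(n_metastatic),
                 n_nonmetastatic = as.integer(n_nonmetastatic),
                 template_metastatic = template_metastatic,
                 template_nonmetastatic = template_nonmetastatic,
                 jitter = jitter, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Preset cohort configurations
#'
#' Three named presets differing only in how the SUV and ADC texture
#' correlation lengths are split between the classes:
#' \describe{
#'   \item{strong}{metastatic cases get a long SUV correlation length (6 mm:
#'     locally smooth uptake, low GLCM entropy) and a short ADC correlation
#'     length (1.2 mm: locally heterogeneous diffusion, high GLCM entropy);
#'     the non-metastatic template is the mirror image. This plants the
#'     low-SUV-entropy / high-ADC-entropy metastatic signature. Note that a
#'     correlation-length contrast moves the whole second-order feature
#'     family together, not GLCM entropy in isolation (see the methods
#'     vignette).}
#'   \item{moderate}{the same split at 4 mm vs 2 mm, a weaker effect.}
#'   \item{null}{both classes share the 3 mm default everywhere; no class
#'     difference exists, for false-positive-rate testing.}
#' }
#' T1w/T2w/DWI textures never differ between classes.
#'
#' @param preset `"strong"`, `"moderate"` or `"null"`.
#' @param n_metastatic,n_nonmetastatic class sizes (default 10/10).
#' @param seed global cohort seed.
#' @param jitter per-case fractional parameter jitter.
#' @param grid_shape,spacing,semi_axes passed to [phantom_config()].
#' @return A [cohort_config].
#' @export
cohort_preset <- function(preset = c("strong", "moderate", "null"),
                          n_metastatic = 10L, n_nonmetastatic = 10L,
                          seed = 1L, jitter = 0.15,
                          grid_shape = c(32L, 32L, 24L),
                          spacing = c(2, 2, 2),
                          semi_axes = c(18, 14, 20)) {
  preset <- match.arg(preset)
  ell <- switch(preset,
    strong   = list(long = 6, short = 1.2),
    moderate = list(long = 4, short = 2),
    null     = list(long = 3, short = 3))
  met <- default_modality_params()
  non <- default_modality_params()
  met$suv$corr_length_mm <- ell$long   # smooth uptake -> low SUV entropy
  met$adc$corr_length_mm <- ell$short  # rough diffusion -> high ADC entropy
  non$suv$corr_length_mm <- ell$short
  non$adc$corr_length_mm <- ell$long
  cohort_config(
    n_metastatic = n_metastatic, n_nonmetastatic = n_nonmetastatic,
    template_metastatic = phantom_config(grid_shape = grid_shape,
                                         spacing = spacing,
                                         semi_axes = semi_axes,
                                         modalities = met),
    template_nonmetastatic = phantom_config(grid_shape = grid_shape,
                                            spacing = spacing,
                                            semi_axes = semi_axes,
                                            modalities = non),
    jitter = jitter, seed = seed)
}

jitter_template <- function(template, jitter) {
  # caller has already seeded the per-case stream; draw in a fixed order
  jf <- function(k) stats::runif(k, 1 - jitter, 1 + jitter)
  semi <- template$semi_axes * jf(3L)
  half_extent <- (template$grid_shape - 1) * template$spacing / 2
  semi <- pmin(semi, half_extent)
  mods <- template$modalities
  for (m in intersect(GOJRAD_MODALITIES, names(mods))) {
    f <- jf(4L)
    mods[[m]]$mean <- mods[[m]]$mean * f[1]
    mods[[m]]$amplitude <- mods[[m]]$amplitude * f[2]
    mods[[m]]$corr_length_mm <- mods[[m]]$corr_length_mm * f[3]
    mods[[m]]$noise_sd <- mods[[m]]$noise_sd * f[4]
    if (!is.null(mods[[m]]$rough_length_mm))
      mods[[m]]$rough_length_mm <- mods[[m]]$rough_length_mm * jf(1L)
  }
  list(semi_axes = semi, modalities = mods)
}

#' Generate a labelled synthetic cohort
#'
#' Non-metastatic cases come first, then metastatic, with ids `case01`,
#' `case02`, ... Case `i` uses the seed `config$seed + i` both for its
#' parameter jitter and (through a derived phantom seed) for its texture
#' fields, so identical configs give bit-identical cohorts.
#'
#' @param config a [cohort_config] (e.g. from [cohort_preset()]).
#' @return A labelled [cohort].
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n_total <- config$n_nonmetastatic + config$n_metastatic
  if (n_total == 0L) return(cohort())
  labels <- rep(c(FALSE, TRUE),
                c(config$n_nonmetastatic, config$n_metastatic))
  cases <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    template <- if (labels[i]) config$template_metastatic else
      config$template_nonmetastatic
    case_seed <- config$seed + i
    set.seed(case_seed)
    jt <- jitter_template(template, config$jitter)
    phantom_seed <- sample.int(.Machine$integer.max - 1L, 1L)
    pc <- phantom_config(grid_shape = template$grid_shape,
                         spacing = template$spacing,
                         semi_axes = jt$semi_axes,
                         modalities = jt$modalities,
                         seed = phantom_seed)
    ph <- generate_phantom(pc)
    cases[[i]] <- case_record(sprintf("case%02d", i), ph$images, ph$mask,
                              metastatic = labels[i])
  }
  cohort(cases)
}

#' Write a cohort to NIfTI files plus a CSV manifest
#'
#' One NIfTI file per modality plus one for the mask, named
#' `<case_id>_<modality>.nii.gz` and `<case_id>_mask.nii.gz`, and a
#' `manifest.csv` readable by [read_manifest()].
#'
#' @param x a [cohort].
#' @param directory output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(x, directory) {
  stopifnot(inherits(x, "cohort"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(x$cases, function(cs) {
    row <- stats::setNames(as.list(rep("", length(GOJRAD_MODALITIES))),
                           GOJRAD_MODALITIES)
    for (m in names(cs$images)) {
      fn <- sprintf("%s_%s.nii.gz", cs$case_id, m)
      write_nifti_volume(cs$images[[m]]$data, cs$images[[m]]$spacing,
                         file.path(directory, fn))
      row[[m]] <- fn
    }
    mn <- sprintf("%s_mask.nii.gz", cs$case_id)
    write_nifti_volume(cs$mask$data, cs$mask$spacing, file.path(directory, mn))
    c(list(case_id = cs$case_id,
           metastatic = as.integer(cs$metastatic)), row, list(mask = mn))
  })
  header <- c("case_id", "metastatic", GOJRAD_MODALITIES, "mask")
  df <- if (length(rows)) {
    do.call(rbind.data.frame, c(rows, stringsAsFactors = FALSE))
  } else {
    as.data.frame(stats::setNames(rep(list(character()), length(header)),
                                  header))
  }
  manifest <- file.path(directory, "manifest.csv")
  utils::write.csv(df, manifest, row.names = FALSE, quote = FALSE)
  invisible(manifest)
}
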