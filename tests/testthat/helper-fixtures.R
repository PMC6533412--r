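# Small in-code fixtures shared across test files. Everything is generated
# programmatically; nothing is read from disk except files the tests
# themselves write to tempdir().

# A volume whose in-mask voxels take prescribed values. The mask is the
# first `length(values)` voxels of a small grid (column-major order); the
# exterior is filled with `fill`.
vol_with_values <- function(values, spacing = c(1, 1, 1), modality = "suv",
                            dims = NULL, fill = 0) {
  if (is.null(dims)) dims <- c(length(values), 1L, 1L)
  stopifnot(prod(dims) >= length(values))
  a <- array(fill, dims)
  a[seq_along(values)] <- values
  m <- array(0, dims)
  m[seq_along(values)] <- 1
  list(image = volume_image(a, spacing, modality),
       mask = seg_mask(m, spacing))
}

# A small box-shaped mask inside a grid.
box_mask <- function(dims = c(8L, 8L, 6L), lo = c(3L, 3L, 2L),
                     hi = c(6L, 6L, 5L), spacing = c(1, 1, 1)) {
  m <- array(0, dims)
  m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- 1
  seg_mask(m, spacing)
}

# Fast small-grid phantom configuration (SUV + ADC only unless stated).
small_phantom_config <- function(seed = 1L, mods = c("suv", "adc"),
                                 ell = NULL) {
  pars <- default_modality_params()[mods]
  if (!is.null(ell)) for (m in names(pars)) pars[[m]]$corr_length_mm <- ell
  phantom_config(grid_shape = c(16L, 16L, 12L), spacing = c(2, 2, 2),
                 semi_axes = c(10, 9, 9), modalities = pars, seed = seed)
}

# Fast small-grid labelled cohort (strong/moderate/null presets).
small_cohort <- function(preset = "strong", n = 3L, seed = 1L,
                         jitter = 0.15) {
  generate_cohort(cohort_preset(preset, n_metastatic = n,
                                n_nonmetastatic = n, seed = seed,
                                jitter = jitter,
                                grid_shape = c(16L, 16L, 12L),
                                spacing = c(2, 2, 2),
                                semi_axes = c(10, 9, 9)))
}

# Independent brute-force oracle for the 12 GLCM features: plain double
# loop over all (i, j) cells, written without reusing any package helper.
brute_force_glcm_features <- function(p) {
  ng <- nrow(p)
  ent <- con <- hom <- homn <- asm <- javg <- idiff <- idiffn <- acor <- 0
  for (i in seq_len(ng)) for (j in seq_len(ng)) {
    v <- p[i, j]
    if (v > 0) ent <- ent - v * log2(v)
    con <- con + (i - j)^2 * v
    hom <- hom + v / (1 + (i - j)^2)
    homn <- homn + v / (1 + ((i - j) / ng)^2)
    asm <- asm + v^2
    javg <- javg + i * v
    idiff <- idiff + v / (1 + abs(i - j))
    idiffn <- idiffn + v / (1 + abs(i - j) / ng)
    acor <- acor + i * j * v
  }
  jvar <- 0
  for (i in seq_len(ng)) for (j in seq_len(ng))
    jvar <- jvar + (i - javg)^2 * p[i, j]
  px <- rep(0, ng)
  for (i in seq_len(ng)) for (j in seq_len(ng)) px[i] <- px[i] + p[i, j]
  mux <- sum(seq_len(ng) * px)
  sig2 <- sum((seq_len(ng) - mux)^2 * px)
  corr <- if (sig2 > 0) (acor - mux^2) / sig2 else 0
  c(glcm_entropy = ent, glcm_contrast = con, glcm_homogeneity = hom,
    glcm_homogeneity_norm = homn, glcm_asm = asm, glcm_joint_max = max(p),
    glcm_joint_avg = javg, glcm_joint_var = jvar, glcm_inv_diff = idiff,
    glcm_inv_diff_norm = idiffn, glcm_correlation = corr,
    glcm_autocorrelation = acor)
}

# Random symmetric normalized co-occurrence matrix wrapped as the package's
# glcm_matrix object.
random_glcm <- function(ng = 8L) {
  m <- matrix(stats::runif(ng * ng), ng, ng)
  m <- m + t(m)
  m <- m / sum(m)
  structure(list(p = m, n_levels = ng, distance = 1L, n_pairs = NA_real_),
            class = "glcm_matrix")
}
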