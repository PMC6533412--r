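# Internal array helpers shared by the phantom generator, GLCM engine and
# morphology code. All volumes are plain 3-D arrays in (x, y, z) order with
# 0-based voxel indices implied by the file layout; physical positions are
# voxel index times spacing (mm).

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Shift a 3-D array by an integer voxel offset, zero-filling
#'
#' @param a 3-D array.
#' @param d integer offset of length 3; `out[i] = a[i - d]` where defined.
#' @return array of the same dimension.
#' @keywords internal
#' @noRd
shift_array <- function(a, d) {
  dm <- dim(a)
  stopifnot(length(dm) == 3L, length(d) == 3L)
  out <- array(0, dm)
  src <- dst <- vector("list", 3L)
  for (ax in 1:3) {
    o <- as.integer(d[ax])
    if (abs(o) >= dm[ax]) return(out)
    if (o >= 0L) {
      dst[[ax]] <- (1L + o):dm[ax]; src[[ax]] <- 1L:(dm[ax] - o)
    } else {
      dst[[ax]] <- 1L:(dm[ax] + o); src[[ax]] <- (1L - o):dm[ax]
    }
  }
  out[dst[[1L]], dst[[2L]], dst[[3L]]] <- a[src[[1L]], src[[2L]], src[[3L]]]
  out
}

#' Separable Gaussian smoothing of a 3-D array
#'
#' Truncated (3 sigma) normalized Gaussian kernel applied along each axis in
#' turn; zero padding at the borders. `sigma_vox` is the kernel standard
#' deviation in voxels per axis; a non-positive sigma skips that axis.
#'
#' @keywords internal
#' @noRd
gaussian_smooth <- function(a, sigma_vox) {
  stopifnot(length(sigma_vox) == 3L)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (!is.finite(s) || s <= 0) next
    r <- max(1L, as.integer(ceiling(3 * s)))
    off <- (-r):r
    w <- exp(-off^2 / (2 * s^2))
    w <- w / sum(w)
    acc <- array(0, dim(a))
    for (k in seq_along(off)) {
      d <- c(0L, 0L, 0L)
      d[ax] <- off[k]
      acc <- acc + w[k] * shift_array(a, d)
    }
    a <- acc
  }
  a
}

# The 13 unique 3-D displacement vectors at Chebyshev distance 1 (half of the
# 26-neighbourhood, one per opposite pair).
glcm_directions <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[!(g[, 1] == 0 & g[, 2] == 0 & g[, 3] == 0), , drop = FALSE]
  keep <- g[, 3] > 0 | (g[, 3] == 0 & g[, 2] > 0) |
    (g[, 3] == 0 & g[, 2] == 0 & g[, 1] > 0)
  unname(g[keep, , drop = FALSE])
}

# The full 26-neighbourhood (or the 6-connected cross) as an offset matrix.
neighbourhood_offsets <- function(connectivity = 26L) {
  if (connectivity == 6L) {
    rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
          c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  } else if (connectivity == 26L) {
    g <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    unname(g[rowSums(abs(g)) > 0, , drop = FALSE])
  } else {
    stop("connectivity must be 6 or 26", call. = FALSE)
  }
}
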