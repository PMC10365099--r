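#' Separable Gaussian smoothing of a 3D volume
#'
#' Convolves a volume with an isotropic Gaussian of the stated full width
#' at half maximum (sigma = FWHM / 2.3548, converted from mm to voxels),
#' applied separably along each axis with nearest-edge padding.
#'
#' @param vol 3D numeric array
#' @param fwhm_mm kernel FWHM in mm (>= 0; 0 returns the input)
#' @param voxel_mm voxel size in mm (scalar or length 3)
#' @return smoothed array of the same dimensions
#' @export
gaussian_smooth_3d <- function(vol, fwhm_mm, voxel_mm = 1.6) {
  if (fwhm_mm < 0) stop("fwhm_mm must be non-negative")
  if (fwhm_mm == 0) return(vol)
  d <- dim(vol)
  if (length(d) != 3) stop("vol must be a 3D array")
  voxel_mm <- rep(voxel_mm, length.out = 3)
  for (ax in 1:3) {
    sigma <- fwhm_mm / 2.3548 / voxel_mm[ax]
    S <- smoothing_operator(d[ax], sigma)
    vol <- apply_along_axis(vol, ax, S)
  }
  vol
}

# dense 1D smoothing operator with nearest-edge (replicate) padding folded
# into the boundary rows
smoothing_operator <- function(n, sigma) {
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    idx <- pmin(pmax(i + seq(-r, r), 1L), n) # clamp = nearest-edge padding
    for (j in seq_along(idx)) S[i, idx[j]] <- S[i, idx[j]] + k[j]
  }
  S
}

apply_along_axis <- function(vol, ax, S) {
  d <- dim(vol)
  perm <- c(ax, setdiff(1:3, ax))
  v <- aperm(vol, perm)
  v <- matrix(v, d[ax])
  v <- S %*% v
  v <- array(v, d[perm])
  aperm(v, order(perm))
}

#' Gaussian smoothing of a 4D multi-echo image
#'
#' Each echo volume is smoothed independently (see [gaussian_smooth_3d()]).
#' Used only to produce the smooth copy from which the flip-angle map is
#' estimated; spectral fitting always uses the unsmoothed (raw or
#' TV-denoised) data.
#'
#' @param img4d 4D array, 4th dimension = echoes
#' @param fwhm_mm kernel FWHM in mm
#' @param voxel_mm voxel size in mm
#' @return smoothed 4D array
#' @export
gaussian_smooth_4d <- function(img4d, fwhm_mm = 4.8, voxel_mm = 1.6) {
  d <- dim(img4d)
  if (length(d) != 4) stop("img4d must be a 4D array")
  for (e in seq_len(d[4]))
    img4d[, , , e] <- gaussian_smooth_3d(img4d[, , , e], fwhm_mm, voxel_mm)
  img4d
}

#' Per-voxel refocusing flip-angle estimate
#'
#' For each of the 15 coarse-grid flip angles, the signal is fitted by
#' unregularized NNLS against that angle's dictionary; the 15 mean squared
#' errors are interpolated by a cubic spline, the interpolated curve is
#' evaluated densely (0.01 degree steps) and its global minimum is snapped
#' to the nearest fine-grid key. Boundary minima at 90 or 180 degrees are
#' accepted as-is; ties go to the smaller angle.
#'
#' @param signal echo train of length `n_echoes`
#' @param bank an [fa_bank()]
#' @return estimated flip angle in degrees, or `NA` for an all-zero signal
#' @export
estimate_fa_voxel <- function(signal, bank) {
  if (all(signal == 0)) return(NA_real_)
  est <- estimate_fa_batch(matrix(signal, ncol = 1), bank)
  est[1]
}

# vectorized FA estimation over columns of Y (n_echoes x n_vox)
estimate_fa_batch <- function(Y, bank) {
  coarse <- bank$coarse
  mse <- matrix(0, length(coarse), ncol(Y))
  for (i in seq_along(coarse)) {
    # exact coarse-angle matrices (cached in the bank alongside fine keys)
    A <- bank_matrix(bank, coarse[i])
    mse[i, ] <- cpp_nnls_mse(A, Y)
  }
  dense <- seq(min(coarse), max(coarse), by = 0.01)
  out <- numeric(ncol(Y))
  for (v in seq_len(ncol(Y))) {
    m <- mse[, v]
    # an exact fit at a coarse angle is a global minimum (MSE >= 0): take
    # it directly rather than risk spline undershoot near the boundary;
    # threshold on the signal scale, far below any noise floor
    if (min(m) <= 1e-8 * mean(Y[, v]^2)) {
      fa_hat <- coarse[which.min(m)]
    } else {
      sf <- stats::splinefun(coarse, m, method = "fmm")
      curve <- sf(dense)
      fa_hat <- dense[which.min(curve)] # first index on ties = smaller FA
    }
    out[v] <- bank_key(bank, fa_hat)
  }
  out
}

#' Flip-angle map of a multi-echo volume
#'
#' Smooths the 4D data with a Gaussian kernel (FWHM `fwhm_mm`), then runs
#' [estimate_fa_voxel()] on every masked voxel of the smoothed copy.
#'
#' @param img4d 4D multi-echo array
#' @param mask logical/integer 3D array of voxels to fit
#' @param bank an [fa_bank()]
#' @param fwhm_mm smoothing FWHM in mm
#' @param voxel_mm voxel size in mm
#' @return object of class `"fa_map"`: list with `fa` (3D array, `NA`
#'   where unfitted) and `mask`
#' @export
estimate_fa_map <- function(img4d, mask, bank, fwhm_mm = 4.8,
                            voxel_mm = 1.6) {
  d <- dim(img4d)
  if (length(d) != 4) stop("img4d must be a 4D array")
  if (!all(dim(mask) == d[1:3])) stop("mask and image shapes differ")
  mask <- array(as.logical(mask), d[1:3])
  fa <- array(NA_real_, d[1:3])
  if (!any(mask)) {
    warning("empty mask: no voxels to fit")
    return(structure(list(fa = fa, mask = mask), class = "fa_map"))
  }
  sm <- gaussian_smooth_4d(img4d, fwhm_mm, voxel_mm)
  idx <- which(mask)
  Y <- t(matrix(sm, prod(d[1:3]), d[4])[idx, , drop = FALSE])
  nz <- colSums(Y != 0) > 0
  est <- rep(NA_real_, length(idx))
  if (any(nz)) est[nz] <- estimate_fa_batch(Y[, nz, drop = FALSE], bank)
  fa[idx] <- est
  structure(list(fa = fa, mask = mask), class = "fa_map")
}

#' @export
print.fa_map <- function(x, ...) {
  v <- x$fa[x$mask]
  cat(sprintf("Flip-angle map: %d fitted voxels, median %.2f deg (%.2f-%.2f)\n",
              sum(!is.na(v)), stats::median(v, na.rm = TRUE),
              min(v, na.rm = TRUE), max(v, na.rm = TRUE)))
  invisible(x)
}
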