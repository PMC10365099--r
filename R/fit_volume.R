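#' Voxelwise spectral fitting of a multi-echo volume
#'
#' Runs the configured spectrum estimator on every masked voxel: the
#' dictionary is looked up per voxel from the flip-angle map (nearest
#' fine-grid key) and voxels sharing a key are fitted in one batched call.
#' Voxels without a flip-angle estimate, or with all-zero signal, are
#' skipped and flagged.
#'
#' @param img4d 4D multi-echo array (raw or denoised)
#' @param mask 3D mask of voxels to fit
#' @param fa_map an `"fa_map"` from [estimate_fa_map()], or a scalar flip
#'   angle applied everywhere
#' @param bank an [fa_bank()]
#' @param config a [fit_config()]
#' @param model trained `"miml_model"` (for `method = "miml"`)
#' @return object of class `"t2spectrum_map"`: `weights` (`n_t2 x n_vox`),
#'   `vox_idx` (linear indices into the volume), `dims`, `grid`, `lambda`,
#'   `method`, `skipped` (indices of flagged voxels)
#' @export
fit_volume <- function(img4d, mask, fa_map, bank,
                       config = fit_config(), model = NULL) {
  d <- dim(img4d)
  if (length(d) != 4) stop("img4d must be a 4D array")
  mask <- array(as.logical(mask), d[1:3])
  idx <- which(mask)
  empty <- function(skipped = integer(0)) {
    structure(list(weights = matrix(0, length(bank$grid), 0),
                   vox_idx = integer(0), dims = d[1:3], grid = bank$grid,
                   lambda = numeric(0), method = config$method,
                   skipped = skipped),
              class = "t2spectrum_map")
  }
  if (!length(idx)) return(empty())
  fa_vals <- if (inherits(fa_map, "fa_map")) fa_map$fa[idx]
             else rep(fa_map[1], length(idx))
  Y <- t(matrix(img4d, prod(d[1:3]), d[4])[idx, , drop = FALSE])
  ok <- !is.na(fa_vals) & colSums(Y != 0) > 0
  skipped <- idx[!ok]
  if (!any(ok)) return(empty(skipped))
  idx <- idx[ok]; fa_vals <- fa_vals[ok]; Y <- Y[, ok, drop = FALSE]

  if (config$method == "miml") {
    if (is.null(model)) stop("method 'miml' needs a trained model")
    W <- predict(model, Y)
    return(structure(list(weights = W, vox_idx = idx, dims = d[1:3],
                          grid = bank$grid,
                          lambda = rep(NA_real_, length(idx)),
                          method = "miml", skipped = skipped),
                     class = "t2spectrum_map"))
  }
  keys <- vapply(fa_vals, function(f) bank_key(bank, f), numeric(1))
  W <- matrix(0, length(bank$grid), length(idx))
  lam <- numeric(length(idx))
  for (k in unique(keys)) {
    sel <- which(keys == k)
    A <- bank_matrix(bank, k)
    lg <- lambda_grid(A, config)
    res <- if (config$method == "chi2")
      cpp_chi2_select(A, Y[, sel, drop = FALSE], lg, config$chi2_factor,
                      config$chi2_rtol)
    else
      cpp_lcurve_select(A, Y[, sel, drop = FALSE], lg)
    W[, sel] <- res$x
    lam[sel] <- res$lambda
  }
  structure(list(weights = W, vox_idx = idx, dims = d[1:3], grid = bank$grid,
                 lambda = lam, method = config$method, skipped = skipped),
            class = "t2spectrum_map")
}

#' @export
print.t2spectrum_map <- function(x, ...) {
  cat(sprintf("T2 spectrum map (%s): %d fitted voxels, %d skipped, grid %d\n",
              x$method, length(x$vox_idx), length(x$skipped),
              length(x$grid)))
  invisible(x)
}

#' Spectrum map as a 4D array
#'
#' @param spectrum_map a `"t2spectrum_map"`
#' @return 4D array `(nx, ny, nz, n_t2)`, `NA` outside fitted voxels
#' @export
spectrum_map_array <- function(spectrum_map) {
  sm <- spectrum_map
  out <- array(NA_real_, c(sm$dims, length(sm$grid)))
  nvox <- prod(sm$dims)
  for (j in seq_along(sm$grid))
    out[sm$vox_idx + (j - 1) * nvox] <- sm$weights[j, ]
  out
}
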