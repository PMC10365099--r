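#' Non-negative least squares
#'
#' Solves `min ||A x - y||^2` subject to `x >= 0` by an active-set
#' (Lawson-Hanson type) iteration on the normal equations, implemented in
#' C++ for the per-voxel problem sizes of multi-echo relaxometry.
#'
#' @param A design matrix (dictionary), rows = echoes, columns = T2 bins
#' @param y observed signal, length `nrow(A)`
#' @return non-negative solution vector of length `ncol(A)`
#' @export
nnls <- function(A, y) {
  A <- as.matrix(A)
  if (length(y) != nrow(A)) stop("length(y) must equal nrow(A)")
  drop(cpp_nnls(A, as.numeric(y)))
}

#' Tikhonov-regularized NNLS
#'
#' Solves `min ||A x - y||^2 + lam^2 ||x||^2` with `x >= 0`, i.e. NNLS on
#' the system augmented with `lam` times the identity. The reported
#' residual is the data term `||A x - y||^2` only.
#'
#' @inheritParams nnls
#' @param lam regularization weight (>= 0)
#' @return list with `weights`, `lambda`, `resid2` (data residual) and
#'   `xnorm2`
#' @export
reg_nnls <- function(A, y, lam) {
  A <- as.matrix(A)
  if (length(y) != nrow(A)) stop("length(y) must equal nrow(A)")
  if (length(lam) != 1 || lam < 0) stop("lam must be a non-negative scalar")
  x <- drop(cpp_reg_nnls(A, as.numeric(y), lam))
  r <- y - A %*% x
  list(weights = x, lambda = lam, resid2 = sum(r^2), xnorm2 = sum(x^2))
}

#' Spectral-fit configuration
#'
#' Bundles the regularization-selection settings shared by the fitting
#' front ends. The chi-square criterion keeps the largest lambda whose data
#' residual stays within `chi2_factor` times the unregularized minimum;
#' the L-curve criterion picks the maximum-curvature corner of the
#' (log residual-norm^2, log solution-norm^2) curve. The lambda grid is
#' log-spaced and anchored to the dictionary scale (its maximum column
#' norm), spanning under- to over-regularization.
#'
#' @param method one of `"chi2"`, `"lcurve"`, `"miml"`
#' @param chi2_factor target residual inflation factor (> 1)
#' @param n_lambda number of lambda grid points
#' @param lambda_span relative span of the grid, multiplied by the
#'   dictionary reference scale
#' @param chi2_rtol relative tolerance on the achieved factor during
#'   bisection refinement
#' @return object of class `"fit_config"`
#' @export
fit_config <- function(method = c("chi2", "lcurve", "miml"),
                       chi2_factor = 1.02, n_lambda = 60,
                       lambda_span = c(1e-5, 10), chi2_rtol = 1e-3) {
  method <- match.arg(method)
  if (chi2_factor <= 1) stop("chi2_factor must be > 1")
  if (n_lambda < 2) stop("n_lambda must be >= 2")
  if (length(lambda_span) != 2 || any(lambda_span <= 0) ||
      diff(lambda_span) <= 0)
    stop("lambda_span must be increasing and positive")
  structure(list(method = method, chi2_factor = chi2_factor,
                 n_lambda = as.integer(n_lambda), lambda_span = lambda_span,
                 chi2_rtol = chi2_rtol),
            class = "fit_config")
}

#' Lambda grid anchored to a dictionary
#'
#' @param A dictionary matrix
#' @param cfg a [fit_config()]
#' @return strictly increasing vector of `n_lambda` positive lambdas
#' @export
lambda_grid <- function(A, cfg = fit_config()) {
  lam_ref <- max(sqrt(colSums(A^2)))
  exp(seq(log(cfg$lambda_span[1] * lam_ref), log(cfg$lambda_span[2] * lam_ref),
          length.out = cfg$n_lambda))
}

#' Chi-square selection of the regularization weight
#'
#' Computes the unregularized residual `chi2_min`, then returns the
#' regularized spectrum at the largest lambda whose data residual does not
#' exceed `chi2_factor * chi2_min` (grid bracketing plus bisection). A
#' perfect unregularized fit is flagged `degenerate` and returned at the
#' smallest grid lambda.
#'
#' @inheritParams nnls
#' @param cfg a [fit_config()]
#' @return list with `weights`, `lambda`, `resid2`, `degenerate`
#' @export
select_lambda_chi2 <- function(A, y, cfg = fit_config()) {
  if (all(y == 0)) stop("signal is identically zero")
  res <- cpp_chi2_select(as.matrix(A), matrix(as.numeric(y)),
                         lambda_grid(A, cfg), cfg$chi2_factor, cfg$chi2_rtol)
  list(weights = drop(res$x), lambda = res$lambda[1], resid2 = res$resid2[1],
       degenerate = res$degenerate[1] == 1L)
}

#' L-curve selection of the regularization weight
#'
#' Evaluates the regularized fit over the lambda grid, locates the corner
#' of the L-curve by maximum discrete Menger curvature over consecutive
#' log-log triplets, and refines it by golden-section search within the
#' bracketing interval. Degenerate (flat or collinear) curves fall back to
#' the smallest grid lambda with `fallback = TRUE`.
#'
#' @inheritParams select_lambda_chi2
#' @return list with `weights`, `lambda`, `resid2`, `fallback`
#' @export
select_lambda_lcurve <- function(A, y, cfg = fit_config(method = "lcurve")) {
  if (all(y == 0)) stop("signal is identically zero")
  res <- cpp_lcurve_select(as.matrix(A), matrix(as.numeric(y)),
                           lambda_grid(A, cfg))
  list(weights = drop(res$x), lambda = res$lambda[1], resid2 = res$resid2[1],
       fallback = res$fallback[1] == 1L)
}
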