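#' Fit a multi-component T2 spectrum to one echo train
#'
#' The front door of the package: estimates the non-negative T2 spectrum of
#' a single multi-echo signal. With `method = "chi2"` or `"lcurve"` the fit
#' is Tikhonov-regularized NNLS against the EPG dictionary for the voxel's
#' refocusing flip angle, with the regularization weight chosen by the
#' chi-square residual criterion or the L-curve corner. With
#' `method = "miml"` the spectrum is predicted by a trained
#' model-informed multilayer perceptron (see [train_mlp()]); the returned
#' spectrum is then a unit-sum distribution.
#'
#' @param y numeric echo train of length `protocol$n_echoes`
#' @param fa refocusing flip angle in degrees used to pick the dictionary
#'   (typically from [estimate_fa_map()]); the nearest fine-grid key is used
#' @param bank an [fa_bank()]; built from defaults when `NULL`
#' @param method spectrum estimator
#' @param config a [fit_config()]
#' @param model a trained `"miml_model"`, required for `method = "miml"`
#' @param protocol protocol used when `bank` is `NULL`
#' @return an object of class `"t2fit"` with the spectrum weights, the grid,
#'   the selected lambda (NNLS methods), the dictionary key and residuals.
#'   Supports `coef`, `fitted`, `residuals`, `predict`, `summary`, `plot`
#'   and `simulate`.
#' @examples
#' p <- t2_protocol()
#' g <- t2_grid()
#' A <- build_dictionary(p, g, 180)
#' y <- A %*% (dnorm(log(g), log(80), 0.1) / sum(dnorm(log(g), log(80), 0.1)))
#' f <- t2fit(drop(y), fa = 180, protocol = p)
#' summary(f)
#' @export
t2fit <- function(y, fa = 180, bank = NULL,
                  method = c("chi2", "lcurve", "miml"),
                  config = NULL, model = NULL, protocol = t2_protocol()) {
  method <- match.arg(method)
  if (is.null(bank)) bank <- fa_bank(protocol)
  if (length(y) != bank$protocol$n_echoes)
    stop("signal length must equal the protocol echo count")
  if (all(y == 0)) stop("signal is identically zero")
  if (is.null(config))
    config <- fit_config(method = if (method == "miml") "miml" else method)
  hit <- bank_lookup(bank, fa)
  if (method == "miml") {
    if (is.null(model)) stop("method 'miml' needs a trained model")
    w <- drop(predict(model, matrix(y, ncol = 1)))
    fitted_sig <- drop(hit$A %*% w)
    # distribution-scale prediction: rescale fitted signal to the data
    s <- sum(fitted_sig * y) / sum(fitted_sig^2)
    out <- list(weights = w * s, lambda = NA_real_,
                resid2 = sum((y - s * fitted_sig)^2), flag = FALSE)
  } else if (method == "chi2") {
    sel <- select_lambda_chi2(hit$A, y, config)
    out <- list(weights = sel$weights, lambda = sel$lambda,
                resid2 = sel$resid2, flag = sel$degenerate)
  } else {
    sel <- select_lambda_lcurve(hit$A, y, config)
    out <- list(weights = sel$weights, lambda = sel$lambda,
                resid2 = sel$resid2, flag = sel$fallback)
  }
  structure(list(weights = out$weights, grid = bank$grid,
                 lambda = out$lambda, resid2 = out$resid2, flag = out$flag,
                 method = method, fa = fa, fa_key = hit$key, y = y,
                 A = hit$A, protocol = bank$protocol),
            class = "t2fit")
}

#' @export
coef.t2fit <- function(object, ...) {
  stats::setNames(object$weights, sprintf("T2_%.3g", object$grid))
}

#' @export
fitted.t2fit <- function(object, ...) drop(object$A %*% object$weights)

#' @export
residuals.t2fit <- function(object, ...) object$y - fitted(object)

#' Predict echo amplitudes from a fitted spectrum
#'
#' Evaluates the fitted spectrum through the EPG forward model, optionally
#' at a different refocusing flip angle or protocol than the fit.
#'
#' @param object a `"t2fit"`
#' @param fa flip angle in degrees (defaults to the fitted one)
#' @param protocol protocol (defaults to the fitted one)
#' @param ... unused
#' @return predicted echo amplitude vector
#' @export
predict.t2fit <- function(object, fa = NULL, protocol = NULL, ...) {
  if (is.null(fa) && is.null(protocol)) return(fitted(object))
  if (is.null(fa)) fa <- object$fa_key
  if (is.null(protocol)) protocol <- object$protocol
  A <- epg_signal_matrix(object$grid, protocol$t1_assumed, fa, protocol)
  drop(A %*% object$weights)
}

#' Simulate noisy echo trains from a fitted spectrum
#'
#' Draws Rician magnitude noise around the fitted noiseless signal at a
#' given first-echo signal-to-noise ratio.
#'
#' @param object a `"t2fit"`
#' @param nsim number of replicates
#' @param seed optional RNG seed
#' @param snr first-echo signal-to-noise ratio
#' @param ... unused
#' @return matrix `n_echoes x nsim`
#' @export
simulate.t2fit <- function(object, nsim = 1, seed = NULL, snr = 100, ...) {
  if (!is.null(seed)) set.seed(seed)
  s <- fitted(object)
  sigma <- s[1] / snr
  add_rician_noise(matrix(rep(s, nsim), length(s)), sigma)
}

#' @export
print.t2fit <- function(x, ...) {
  cat(sprintf("Multi-component T2 fit (%s), FA key %.2f deg\n", x$method,
              x$fa_key))
  cat(sprintf("  grid: %d points, %.3g-%.3g ms\n", length(x$grid),
              min(x$grid), max(x$grid)))
  if (!is.na(x$lambda))
    cat(sprintf("  lambda = %.4g, data residual = %.4g\n", x$lambda,
                x$resid2))
  invisible(x)
}

#' @export
summary.t2fit <- function(object, windows = compartment_windows(), ...) {
  out <- list(fit = object,
              t2ie = t2ie(object$weights, object$grid, windows),
              mwf = mwf(object$weights, object$grid, windows),
              total = sum(object$weights))
  class(out) <- "summary.t2fit"
  out
}

#' @export
print.summary.t2fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  T2IE = %.2f ms, MWF = %.3f, total weight = %.4g\n",
              x$t2ie, x$mwf, x$total))
  invisible(x)
}

#' @export
plot.t2fit <- function(x, ...) {
  graphics::plot(x$grid, x$weights, type = "h", log = "x",
                 xlab = "T2 (ms)", ylab = "weight",
                 main = sprintf("T2 spectrum (%s)", x$method), ...)
  graphics::abline(v = c(40, 200), lty = 3, col = "grey40")
  invisible(x)
}
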