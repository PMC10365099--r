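#' Add Rician magnitude noise
#'
#' Magnitude-MRI noise model: the noiseless signal is perturbed by
#' independent Gaussian noise of standard deviation `sigma` on both
#' quadrature channels and the magnitude is taken,
#' `sqrt((s + n1)^2 + n2^2)`.
#'
#' @param s numeric vector/matrix/array of noiseless signal values
#' @param sigma Gaussian channel standard deviation (>= 0)
#' @return noisy values with the same shape as `s`
#' @export
add_rician_noise <- function(s, sigma) {
  if (sigma < 0) stop("sigma must be non-negative")
  if (sigma == 0) return(s)
  n <- length(s)
  out <- sqrt((s + stats::rnorm(n, 0, sigma))^2 + stats::rnorm(n, 0, sigma)^2)
  if (!is.null(dim(s))) dim(out) <- dim(s)
  out
}

# derive a child seed from a base seed, kept within 32-bit integer range
child_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(i)) %% 2147483629)
}
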