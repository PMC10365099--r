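#' Multi-echo spin-echo acquisition protocol
#'
#' Describes the echo-train timing of a CPMG-style multi-echo acquisition:
#' a 90 degree excitation followed by a train of equally spaced refocusing
#' pulses, with echoes read midway between pulses. Defaults mirror a 3D
#' GRASE protocol at 3T (32 echoes, TE1 = dTE = 10.68 ms, TR = 1 s,
#' nominal refocusing flip angle 180 degrees).
#'
#' @param n_echoes number of echoes (>= 1)
#' @param te_min first echo time in ms (> 0)
#' @param delta_te echo spacing in ms (> 0); echo n occurs at
#'   `te_min + (n - 1) * delta_te`
#' @param tr repetition time in ms
#' @param t1_assumed longitudinal relaxation time in ms assumed by the EPG
#'   forward model for magnetization stored longitudinally between pulses.
#'   Set very large (e.g. `1e9`) to disable T1 decay of stimulated pathways.
#' @param fa_nominal nominal (prescribed) refocusing flip angle in degrees
#' @return an object of class `"t2_protocol"`
#' @examples
#' p <- t2_protocol()
#' echo_times(p)[1:4]
#' @export
t2_protocol <- function(n_echoes = 32, te_min = 10.68, delta_te = 10.68,
                        tr = 1000, t1_assumed = 1000, fa_nominal = 180) {
  stopifnot(length(n_echoes) == 1, length(te_min) == 1, length(delta_te) == 1)
  if (n_echoes < 1 || n_echoes != round(n_echoes))
    stop("n_echoes must be a positive integer")
  if (te_min <= 0) stop("te_min must be positive")
  if (delta_te <= 0) stop("delta_te must be positive")
  if (t1_assumed <= 0) stop("t1_assumed must be positive")
  if (tr <= 0) stop("tr must be positive")
  structure(list(n_echoes = as.integer(n_echoes), te_min = te_min,
                 delta_te = delta_te, tr = tr, t1_assumed = t1_assumed,
                 fa_nominal = fa_nominal),
            class = "t2_protocol")
}

#' Echo times of a protocol
#'
#' @param protocol a [t2_protocol()] object
#' @return numeric vector of echo times in ms
#' @export
echo_times <- function(protocol) {
  stopifnot(inherits(protocol, "t2_protocol"))
  protocol$te_min + (seq_len(protocol$n_echoes) - 1) * protocol$delta_te
}

#' @export
print.t2_protocol <- function(x, ...) {
  cat("Multi-echo spin-echo protocol\n")
  cat(sprintf("  echoes: %d, TE1 = %.2f ms, dTE = %.2f ms, TR = %.0f ms\n",
              x$n_echoes, x$te_min, x$delta_te, x$tr))
  cat(sprintf("  nominal FA: %.0f deg, assumed T1: %g ms\n",
              x$fa_nominal, x$t1_assumed))
  invisible(x)
}
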