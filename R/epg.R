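#' Extended Phase Graph echo amplitudes
#'
#' Simulates the echo amplitudes of a CPMG-style multi-echo spin-echo train
#' for one T2 value under imperfect refocusing, using the Extended Phase
#' Graph (EPG) configuration-state recursion. The sequence is an ideal 90
#' degree excitation followed by `n_echoes` refocusing pulses of flip angle
#' `fa` (about an axis 90 degrees from the excitation, the CPMG condition)
#' at spacing `delta_te`; echo n is read midway between pulses n and n+1,
#' i.e. at time `te_min + (n-1) * delta_te`.
#'
#' Transverse configuration states decay with T2 over each half interval;
#' magnetization stored longitudinally by imperfect pulses (the stimulated
#' pathways) decays with T1. Regrowth toward thermal equilibrium during the
#' train is not modeled (echo-train duration is short relative to TR; at
#' 180 degrees longitudinal states never couple back into the transverse
#' plane, so the train is exactly monoexponential for any T1).
#'
#' @param t2 transverse relaxation time in ms (> 0)
#' @param t1 longitudinal relaxation time in ms (> 0); governs stimulated
#'   pathways only
#' @param fa refocusing flip angle in degrees, in (0, 180]
#' @param protocol a [t2_protocol()]
#' @return numeric vector of `n_echoes` non-negative echo amplitudes for
#'   unit initial magnetization
#' @examples
#' p <- t2_protocol()
#' a <- epg_echo_amplitudes(100, 1000, 180, p)
#' all.equal(a, exp(-echo_times(p) / 100))
#' @export
epg_echo_amplitudes <- function(t2, t1, fa, protocol) {
  stopifnot(length(t2) == 1)
  drop(epg_signal_matrix(t2, t1, fa, protocol))
}

#' EPG echo amplitudes for many T2 values at once
#'
#' Vectorized form of [epg_echo_amplitudes()]: runs the EPG recursion for a
#' whole vector of T2 values simultaneously (this is how dictionary columns
#' are produced).
#'
#' @inheritParams epg_echo_amplitudes
#' @param t2 vector of T2 values in ms
#' @return matrix of dimension `n_echoes x length(t2)`
#' @export
epg_signal_matrix <- function(t2, t1, fa, protocol) {
  stopifnot(inherits(protocol, "t2_protocol"))
  if (any(t2 <= 0)) stop("t2 must be positive")
  if (length(t1) != 1 || t1 <= 0) stop("t1 must be a positive scalar")
  if (length(fa) != 1 || fa <= 0 || fa > 180)
    stop("fa must be in (0, 180] degrees")
  ne <- protocol$n_echoes
  nt <- length(t2)
  K <- ne + 1L # configuration orders 0..ne retained: exact over the train
  E2 <- exp(-(protocol$delta_te / 2) / t2) # per half interval, per T2
  E1 <- exp(-(protocol$delta_te / 2) / t1)
  E2m <- matrix(rep(E2, each = K), K, nt)

  a <- fa * pi / 180
  # rotation about x applied to (F+(k), F-(k), Z(k)); excitation was about y
  T11 <- cos(a / 2)^2;  T12 <- sin(a / 2)^2;  T13 <- -1i * sin(a)
  T21 <- T12;           T22 <- T11;           T23 <- 1i * sin(a)
  T31 <- -0.5i * sin(a); T32 <- 0.5i * sin(a); T33 <- cos(a)

  Fp <- matrix(0i, K, nt); Fm <- matrix(0i, K, nt); Z <- matrix(0i, K, nt)
  Fp[1L, ] <- 1 # ideal 90 degree excitation, CPMG phase: F0 real

  amp <- matrix(0, ne, nt)
  for (n in seq_len(ne)) {
    # first half interval: relax, dephase one configuration order
    Fp <- Fp * E2m; Fm <- Fm * E2m; Z <- Z * E1
    Fp <- rbind(Conj(Fm[2L, , drop = FALSE]), Fp[-K, , drop = FALSE])
    Fm <- rbind(Fm[-1L, , drop = FALSE], matrix(0i, 1L, nt))
    # refocusing pulse
    Fp2 <- T11 * Fp + T12 * Fm + T13 * Z
    Fm2 <- T21 * Fp + T22 * Fm + T23 * Z
    Z   <- T31 * Fp + T32 * Fm + T33 * Z
    Fp <- Fp2; Fm <- Fm2
    # second half interval
    Fp <- Fp * E2m; Fm <- Fm * E2m; Z <- Z * E1
    Fp <- rbind(Conj(Fm[2L, , drop = FALSE]), Fp[-K, , drop = FALSE])
    Fm <- rbind(Fm[-1L, , drop = FALSE], matrix(0i, 1L, nt))
    amp[n, ] <- Mod(Fp[1L, ])
  }
  amp
}
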