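#' Logarithmic T2 grid
#'
#' The grid of candidate T2 values on which spectra are represented:
#' `n` points logarithmically spaced between `t2_lo` and `t2_hi`,
#' both endpoints included. Defaults give 60 points from 10 to 2000 ms.
#'
#' @param t2_lo lower bound in ms
#' @param t2_hi upper bound in ms
#' @param n number of grid points (>= 2)
#' @return strictly increasing numeric vector of length `n` with a constant
#'   ratio between consecutive values
#' @examples
#' g <- t2_grid()
#' length(g); range(g)
#' @export
t2_grid <- function(t2_lo = 10, t2_hi = 2000, n = 60) {
  if (n < 2 || n != round(n)) stop("n must be an integer >= 2")
  if (t2_lo <= 0 || t2_hi <= t2_lo) stop("need 0 < t2_lo < t2_hi")
  exp(seq(log(t2_lo), log(t2_hi), length.out = n))
}

#' Flip-angle search grids
#'
#' The coarse grid used for per-voxel flip-angle estimation (15 equally
#' spaced values spanning 90-180 degrees) and the fine grid on which
#' dictionaries are precomputed (step 0.33 degrees from 90, with 180
#' appended so both endpoints of the coarse grid are representable).
#'
#' @param fa_lo,fa_hi coarse-grid endpoints in degrees
#' @param n_coarse number of coarse values
#' @param fine_step fine-grid step in degrees
#' @return list with components `coarse` and `fine`
#' @export
fa_grids <- function(fa_lo = 90, fa_hi = 180, n_coarse = 15,
                     fine_step = 0.33) {
  coarse <- seq(fa_lo, fa_hi, length.out = n_coarse)
  k <- 0:floor((fa_hi - fa_lo) / fine_step)
  fine <- fa_lo + k * fine_step
  if (max(fine) < fa_hi) fine <- c(fine, fa_hi)
  list(coarse = coarse, fine = fine)
}

#' EPG dictionary matrix for one flip angle
#'
#' Column j of the dictionary is the EPG echo train of the j-th grid T2 at
#' the given refocusing flip angle: the linear forward operator mapping a
#' non-negative T2 spectrum to the noiseless multi-echo signal. Columns are
#' not normalized (unit proton density); the spectrum weights carry scale.
#'
#' @param protocol a [t2_protocol()]
#' @param grid T2 grid from [t2_grid()]
#' @param fa refocusing flip angle in degrees, in \[90, 180\]
#' @return matrix of dimension `n_echoes x length(grid)`
#' @export
build_dictionary <- function(protocol, grid, fa) {
  if (fa < 90 || fa > 180) stop("fa must be in [90, 180] degrees")
  epg_signal_matrix(grid, protocol$t1_assumed, fa, protocol)
}

#' Bank of precomputed dictionaries on the fine flip-angle grid
#'
#' Lazily cached collection of dictionary matrices keyed by fine-grid flip
#' angle. [bank_lookup()] returns the matrix whose key is nearest the
#' requested angle (ties to the smaller key); matrices are computed on
#' first use and cached, and lookups are identical to eager construction.
#'
#' @inheritParams build_dictionary
#' @param grids flip-angle grids from [fa_grids()]
#' @return object of class `"fa_bank"`
#' @export
fa_bank <- function(protocol, grid = t2_grid(), grids = fa_grids()) {
  structure(list(protocol = protocol, grid = grid, keys = grids$fine,
                 coarse = grids$coarse, cache = new.env(parent = emptyenv())),
            class = "fa_bank")
}

#' Nearest-key dictionary lookup
#'
#' @param bank an [fa_bank()]
#' @param fa requested flip angle in degrees
#' @return list with the matched `key` (degrees) and the dictionary `A`
#' @export
bank_lookup <- function(bank, fa) {
  stopifnot(inherits(bank, "fa_bank"))
  key <- bank_key(bank, fa)
  list(key = key, A = bank_matrix(bank, key))
}

#' @rdname bank_lookup
#' @export
bank_key <- function(bank, fa) {
  d <- abs(fa - bank$keys)
  # ties (to floating-point precision) go to the smaller key
  min(bank$keys[d <= min(d) + 1e-9])
}

bank_matrix <- function(bank, key) {
  id <- sprintf("fa_%.6f", key)
  A <- bank$cache[[id]]
  if (is.null(A)) {
    A <- build_dictionary(bank$protocol, bank$grid, key)
    assign(id, A, envir = bank$cache)
  }
  A
}

#' @export
print.fa_bank <- function(x, ...) {
  cat(sprintf(
    "EPG dictionary bank: %d fine FA keys (%.2f-%.2f deg), %d x %d matrices\n",
    length(x$keys), min(x$keys), max(x$keys), x$protocol$n_echoes,
    length(x$grid)))
  cat(sprintf("  cached: %d\n", length(ls(x$cache))))
  invisible(x)
}
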