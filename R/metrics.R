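#' Compartment windows on the T2 axis
#'
#' Water pools are assigned by T2: myelin water below `myelin_upper`,
#' intra/extra-cellular water between `myelin_upper` and
#' `free_water_lower`, free water above. Window endpoints are inclusive on
#' both sides. Defaults are the 3T convention (40 and 200 ms).
#'
#' @param myelin_upper upper T2 bound of the myelin pool, ms
#' @param free_water_lower lower T2 bound of the free-water pool, ms
#' @return object of class `"compartment_windows"`
#' @export
compartment_windows <- function(myelin_upper = 40, free_water_lower = 200) {
  if (myelin_upper <= 0 || free_water_lower <= myelin_upper)
    stop("need 0 < myelin_upper < free_water_lower")
  structure(list(myelin_upper = myelin_upper,
                 free_water_lower = free_water_lower),
            class = "compartment_windows")
}

#' Intra/extra-cellular T2 (T2IE)
#'
#' The amplitude-weighted geometric mean of the T2 spectrum restricted to
#' the intra/extra-cellular window:
#' `exp( sum_i w_i log T2_i / sum_i w_i )` over grid points with
#' `myelin_upper <= T2_i <= free_water_lower`. Because the window excludes
#' both myelin and free water, the metric is immune to spectral mass
#' outside it (partial-volume immunity) and invariant to rescaling the
#' weights. Returns `NA` when the window carries no mass.
#'
#' @param weights non-negative spectrum weights
#' @param grid T2 grid in ms, same length as `weights`
#' @param windows a [compartment_windows()]
#' @return T2IE in ms, or `NA_real_` when undefined
#' @export
t2ie <- function(weights, grid, windows = compartment_windows()) {
  stopifnot(length(weights) == length(grid))
  if (any(weights < 0)) stop("weights must be non-negative")
  sel <- grid >= windows$myelin_upper & grid <= windows$free_water_lower
  m <- sum(weights[sel])
  if (m <= 0) return(NA_real_)
  exp(sum(weights[sel] * log(grid[sel])) / m)
}

#' Myelin water fraction
#'
#' Fraction of total spectral mass with T2 below the myelin window bound.
#'
#' @inheritParams t2ie
#' @return fraction in \[0, 1\], or `NA_real_` for zero total mass
#' @export
mwf <- function(weights, grid, windows = compartment_windows()) {
  stopifnot(length(weights) == length(grid))
  if (any(weights < 0)) stop("weights must be non-negative")
  total <- sum(weights)
  if (total <= 0) return(NA_real_)
  sum(weights[grid < windows$myelin_upper]) / total
}

#' Scalar maps from a fitted spectrum map
#'
#' Applies [t2ie()] or [mwf()] voxelwise to the output of [fit_volume()]
#' or [predict_spectrum_map()].
#'
#' @param spectrum_map object of class `"t2spectrum_map"`
#' @param windows a [compartment_windows()]
#' @return 3D array with `NA` outside the mask or where undefined
#' @export
t2ie_map <- function(spectrum_map, windows = compartment_windows()) {
  scalar_map(spectrum_map, windows, t2ie)
}

#' @rdname t2ie_map
#' @export
mwf_map <- function(spectrum_map, windows = compartment_windows()) {
  scalar_map(spectrum_map, windows, mwf)
}

scalar_map <- function(sm, windows, f) {
  stopifnot(inherits(sm, "t2spectrum_map"))
  out <- array(NA_real_, sm$dims)
  if (length(sm$vox_idx))
    out[sm$vox_idx] <- apply(sm$weights, 2, f, grid = sm$grid,
                             windows = windows)
  out
}
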