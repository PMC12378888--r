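#' Axis calibration: the affine point-to-ppm map of one spectral dimension
#'
#' A frequency axis is fully described by the number of points, the spectral
#' width in Hz, the observe (spectrometer) frequency in MHz and the absolute
#' frequency in Hz of the \emph{last} point (the origin, following the
#' NMRPipe header convention). Point index 0 is the downfield (highest ppm)
#' edge; all indices are 0-based.
#'
#' @param n_points number of real points along the axis (> 0)
#' @param sw_hz spectral width in Hz (> 0)
#' @param obs_mhz observe frequency in MHz (> 0)
#' @param origin_hz frequency in Hz of the last point
#' @return an object of class `nmr_axis`
#' @export
new_axis <- function(n_points, sw_hz, obs_mhz, origin_hz) {
  stopifnot_scalar(n_points, "n_points"); stopifnot_scalar(sw_hz, "sw_hz")
  stopifnot_scalar(obs_mhz, "obs_mhz"); stopifnot_scalar(origin_hz, "origin_hz")
  if (n_points < 1 || sw_hz <= 0 || obs_mhz <= 0)
    nmr_stop("axis requires n_points >= 1, sw_hz > 0, obs_mhz > 0")
  structure(list(n_points = as.integer(n_points), sw_hz = sw_hz,
                 obs_mhz = obs_mhz, origin_hz = origin_hz),
            class = "nmr_axis")
}

#' Build an axis from a carrier position
#'
#' The carrier (transmitter offset) sits at the centre of the spectral
#' window; with the downfield-first layout the centre falls on 0-based index
#' `n/2`, whose frequency is `carrier_hz`.
#'
#' @inheritParams new_axis
#' @param carrier_ppm chemical shift of the carrier in ppm
#' @export
axis_from_carrier <- function(n_points, sw_hz, obs_mhz, carrier_ppm) {
  car_hz <- carrier_ppm * obs_mhz
  origin <- car_hz - sw_hz / 2 + sw_hz / n_points
  new_axis(n_points, sw_hz, obs_mhz, origin)
}

#' @export
print.nmr_axis <- function(x, ...) {
  p <- axis_ppm(x)
  cat(sprintf("<nmr_axis> %d pts, sw %.1f Hz, obs %.4f MHz, ppm %.4f .. %.4f\n",
              x$n_points, x$sw_hz, x$obs_mhz, p[1], p[length(p)]))
  invisible(x)
}

#' Chemical shift of every point on an axis
#' @param axis an `nmr_axis`
#' @return numeric vector of ppm values, index 0 (downfield) first
#' @export
axis_ppm <- function(axis) {
  k <- seq_len(axis$n_points) - 1L
  (axis$origin_hz + (axis$n_points - 1L - k) * axis$sw_hz / axis$n_points) /
    axis$obs_mhz
}

#' Convert chemical shift to fractional 0-based point index
#' @param axis an `nmr_axis`
#' @param ppm chemical shift(s) in ppm
#' @export
ppm_to_pt <- function(axis, ppm) {
  (axis$n_points - 1L) - (ppm * axis$obs_mhz - axis$origin_hz) *
    axis$n_points / axis$sw_hz
}

#' Convert fractional 0-based point index to chemical shift
#' @param axis an `nmr_axis`
#' @param pt fractional 0-based index/indices
#' @export
pt_to_ppm <- function(axis, pt) {
  (axis$origin_hz + (axis$n_points - 1L - pt) * axis$sw_hz / axis$n_points) /
    axis$obs_mhz
}

# carrier ppm implied by an axis (centre of the window, index n/2)
axis_carrier_ppm <- function(axis) {
  (axis$origin_hz + (axis$n_points / 2 - 1) * axis$sw_hz / axis$n_points) /
    axis$obs_mhz
}

# restrict an axis to indices [i0, i1] (0-based, inclusive); ppm of kept
# points is unchanged
axis_slice <- function(axis, i0, i1) {
  n_new <- i1 - i0 + 1L
  # frequency of new last point (old index i1)
  f_last <- axis$origin_hz + (axis$n_points - 1L - i1) * axis$sw_hz / axis$n_points
  sw_new <- axis$sw_hz * n_new / axis$n_points
  new_axis(n_new, sw_new, axis$obs_mhz, f_last)
}
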