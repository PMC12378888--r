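#' Acquisition metadata for a 2D / pseudo-3D time-domain dataset
#'
#' Dimension order is (direct, indirect) in all per-dimension vectors.
#'
#' @param n_complex_points integer pair: complex points per FID (direct) and
#'   complex increments (indirect)
#' @param sw_hz numeric pair, spectral widths in Hz
#' @param obs_mhz numeric pair, observe frequencies in MHz
#' @param carrier_ppm numeric pair, carrier positions in ppm
#' @param acquisition_mode indirect quadrature scheme: one of `"states"`,
#'   `"states_tppi"`, `"echo_antiecho"`
#' @param data_type on-disk encoding, `"float64"` (TopSpin >= 3 default,
#'   DTYPA = 2) or `"int32"`
#' @param byte_order `"little"` or `"big"`
#' @param group_delay Bruker digital-filter group delay in points (>= 0)
#' @param n_planes number of pseudo-3D planes (>= 1)
#' @return an object of class `nmr_acq`
#' @export
new_acquisition_meta <- function(n_complex_points, sw_hz, obs_mhz, carrier_ppm,
                                 acquisition_mode = "states",
                                 data_type = "float64",
                                 byte_order = "little",
                                 group_delay = 0, n_planes = 1L) {
  acquisition_mode <- match.arg(acquisition_mode,
                                c("states", "states_tppi", "echo_antiecho"))
  data_type <- match.arg(data_type, c("float64", "int32"))
  byte_order <- match.arg(byte_order, c("little", "big"))
  if (length(n_complex_points) != 2L || any(n_complex_points <= 0))
    nmr_stop("n_complex_points must be two positive integers")
  if (any(sw_hz <= 0) || any(obs_mhz <= 0)) nmr_stop("sw and obs must be > 0")
  if (group_delay < 0) nmr_stop("group_delay must be >= 0")
  if (n_planes < 1) nmr_stop("n_planes must be >= 1")
  structure(list(n_complex_points = as.integer(n_complex_points),
                 sw_hz = as.numeric(sw_hz), obs_mhz = as.numeric(obs_mhz),
                 carrier_ppm = as.numeric(carrier_ppm),
                 acquisition_mode = acquisition_mode, data_type = data_type,
                 byte_order = byte_order, group_delay = group_delay,
                 n_planes = as.integer(n_planes)),
            class = "nmr_acq")
}

#' Time-domain data container
#'
#' @param fid complex array `[plane, row, direct]`: one row per stored FID
#'   (two rows per indirect complex increment, quadrature pairs adjacent)
#' @param meta an `nmr_acq`
#' @return an object of class `nmr_fid`
#' @export
new_timedomain <- function(fid, meta) {
  if (is.matrix(fid)) fid <- array(fid, c(1L, nrow(fid), ncol(fid)))
  stopifnot(length(dim(fid)) == 3L, inherits(meta, "nmr_acq"))
  structure(list(fid = fid, meta = meta), class = "nmr_fid")
}

#' @export
print.nmr_fid <- function(x, ...) {
  d <- dim(x$fid)
  cat(sprintf("<nmr_fid> %d plane(s), %d rows x %d complex points (%s, %s)\n",
              d[1], d[2], d[3], x$meta$acquisition_mode, x$meta$data_type))
  invisible(x)
}
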