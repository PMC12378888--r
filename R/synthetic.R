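# Ground-truth fixture generator: analytic FIDs from declared peak
# parameters, written as genuine Bruker directories so every reader and the
# full pipeline are testable without external data.

#' Declare the ground truth of a synthetic 2D / pseudo-3D dataset
#'
#' @param peaks data frame with columns `x_ppm`, `y_ppm`, `amplitude`,
#'   `r2_x_hz`, `r2_y_hz` (exponential decay rates in 1/s; the Lorentzian
#'   FWHM is `r2/pi` Hz) and optionally `gauss_x_hz`, `gauss_y_hz`
#'   (Gaussian inhomogeneity FWHM in Hz, giving honest Voigt shapes)
#' @param acquisition an `nmr_acq`; the default emulates a 600 MHz HN-HSQC:
#'   sw 8000 x 2000 Hz, obs 600.13 x 60.81 MHz, carriers 4.7 / 118 ppm
#' @param applied_phase list with `nmr_phase` elements `direct` and
#'   `indirect`: the known dephasing baked into the FID (a processor must
#'   apply these to reach absorption mode)
#' @param noise_sigma standard deviation of the complex Gaussian noise added
#'   to every time-domain point
#' @param plane_decay optional list `(delays_s, rate_per_s)`: per-plane peak
#'   scaling `exp(-rate * delay)` (rate recycled per peak)
#' @param plane_scales optional explicit per-plane global scale factors
#' @param axial list `(x_ppm, amp)` adding a t1-independent axial signal
#' @param nus_schedule optional `nmr_nus_schedule` recorded for provenance
#' @param seed RNG seed; fixtures are bit-reproducible from the truth alone
#' @return an object of class `nmr_truth`
#' @export
new_ground_truth <- function(peaks,
                             acquisition = new_acquisition_meta(
                               n_complex_points = c(256L, 64L),
                               sw_hz = c(8000, 2000),
                               obs_mhz = c(600.13, 60.81),
                               carrier_ppm = c(4.7, 118)),
                             applied_phase = list(direct = new_phase(0, 0),
                                                  indirect = new_phase(0, 0)),
                             noise_sigma = 0, plane_decay = NULL,
                             plane_scales = NULL, axial = NULL,
                             nus_schedule = NULL, seed = 1L) {
  peaks <- as.data.frame(peaks)
  need <- c("x_ppm", "y_ppm", "amplitude", "r2_x_hz", "r2_y_hz")
  if (nrow(peaks) > 0L && !all(need %in% names(peaks)))
    nmr_stop("peaks needs columns ", paste(need, collapse = ", "))
  structure(list(peaks = peaks, acquisition = acquisition,
                 applied_phase = applied_phase, noise_sigma = noise_sigma,
                 plane_decay = plane_decay, plane_scales = plane_scales,
                 axial = axial, nus_schedule = nus_schedule,
                 seed = as.integer(seed)),
            class = "nmr_truth")
}

# per-plane scale factor of peak j on plane p
truth_plane_scale <- function(truth, p, j) {
  s <- 1
  if (!is.null(truth$plane_scales)) s <- s * truth$plane_scales[p]
  if (!is.null(truth$plane_decay)) {
    rates <- rep_len(truth$plane_decay$rate_per_s, nrow(truth$peaks))
    s <- s * exp(-rates[j] * truth$plane_decay$delays_s[p])
  }
  s
}

truth_n_planes <- function(truth) {
  if (!is.null(truth$plane_scales)) return(length(truth$plane_scales))
  if (!is.null(truth$plane_decay)) return(length(truth$plane_decay$delays_s))
  truth$acquisition$n_planes
}

#' Simulate the time-domain data of a declared ground truth
#'
#' Each peak contributes `A * exp(i*2*pi*fx*t2 - r2x*t2)` along the direct
#' dimension (with optional Gaussian decay for Voigt shapes), quadrature-
#' encoded indirect evolution at `fy` per the acquisition mode, the declared
#' dephasing, seeded complex Gaussian noise and per-plane scaling. A group
#' delay in the metadata shifts the direct time axis by `-gd` points, which
#' is what the digital-filter compensation must undo.
#'
#' @param truth an `nmr_truth`
#' @return an `nmr_fid`
#' @export
generate_fid <- function(truth) {
  acq <- truth$acquisition
  nd <- acq$n_complex_points[1]; ni <- acq$n_complex_points[2]
  sw2 <- acq$sw_hz[1]; sw1 <- acq$sw_hz[2]
  np <- truth_n_planes(truth)
  pk <- truth$peaks
  fx <- (pk$x_ppm - acq$carrier_ppm[1]) * acq$obs_mhz[1]
  fy <- (pk$y_ppm - acq$carrier_ppm[2]) * acq$obs_mhz[2]
  if (nrow(pk) > 0L && (any(abs(fx) > sw2 / 2) || any(abs(fy) > sw1 / 2)))
    nmr_stop("frequency outside spectral width: fixtures must not alias")
  gx <- if ("gauss_x_hz" %in% names(pk)) pk$gauss_x_hz else rep(0, nrow(pk))
  gy <- if ("gauss_y_hz" %in% names(pk)) pk$gauss_y_hz else rep(0, nrow(pk))
  t2 <- (seq_len(nd) - 1 - acq$group_delay) / sw2
  t1 <- (seq_len(ni) - 1) / sw1
  pd <- truth$applied_phase$direct; pi_ <- truth$applied_phase$indirect
  # dephasing per peak: constant phase at the peak's fractional position
  phx <- (pd$p0_deg + pd$p1_deg * (0.5 - fx / sw2)) * pi / 180
  phy <- (pi_$p0_deg + pi_$p1_deg * (0.5 - fy / sw1)) * pi / 180
  g_sd <- function(fwhm_hz) {            # Gaussian FWHM in Hz -> exp(-a t^2)
    ifelse(fwhm_hz > 0, (pi * fwhm_hz)^2 / (4 * log(2)), 0)
  }
  ax <- g_sd(gx); ay <- g_sd(gy)

  set.seed(truth$seed)
  fid <- array(0i, c(np, 2L * ni, nd))
  for (p in seq_len(np)) {
    plane <- matrix(0i, 2L * ni, nd)
    for (j in seq_len(nrow(pk))) {
      D <- pk$amplitude[j] * truth_plane_scale(truth, p, j) *
        exp((2i * pi * fx[j] - pk$r2_x_hz[j]) * t2 - ax[j] * t2^2 -
            1i * phx[j])
      th <- 2 * pi * fy[j] * t1 - phy[j]
      decay1 <- exp(-pk$r2_y_hz[j] * t1 - ay[j] * t1^2)
      if (acq$acquisition_mode == "echo_antiecho") {
        e <- exp(-1i * th) * decay1
        a <- exp(1i * th) * decay1
        plane[seq(1L, 2L * ni, 2L), ] <- plane[seq(1L, 2L * ni, 2L), ] +
          outer(e, D)
        plane[seq(2L, 2L * ni, 2L), ] <- plane[seq(2L, 2L * ni, 2L), ] +
          outer(a, D)
      } else {
        plane[seq(1L, 2L * ni, 2L), ] <- plane[seq(1L, 2L * ni, 2L), ] +
          outer(cos(th) * decay1, D)
        plane[seq(2L, 2L * ni, 2L), ] <- plane[seq(2L, 2L * ni, 2L), ] +
          outer(sin(th) * decay1, D)
      }
    }
    if (acq$acquisition_mode == "states_tppi") {
      sgn <- rep(rep_len(c(1, -1), ni), each = 2L)
      plane <- plane * sgn
    }
    # axial artifacts do not follow the t1 phase cycling, so they are added
    # after any States-TPPI sign alternation
    if (!is.null(truth$axial)) {
      fa <- (truth$axial$x_ppm - acq$carrier_ppm[1]) * acq$obs_mhz[1]
      Da <- truth$axial$amp * exp((2i * pi * fa - (truth$axial$r2_x_hz %||% 30)) * t2)
      plane[seq(1L, 2L * ni, 2L), ] <- plane[seq(1L, 2L * ni, 2L), ] +
        matrix(Da, ni, nd, byrow = TRUE)
    }
    if (truth$noise_sigma > 0) {
      plane <- plane + complex(
        real = stats::rnorm(length(plane), 0, truth$noise_sigma),
        imaginary = stats::rnorm(length(plane), 0, truth$noise_sigma))
    }
    fid[p, , ] <- plane
  }
  meta <- acq
  meta$n_planes <- np
  if (meta$data_type == "int32") fid <- round(fid)
  new_timedomain(fid, meta)
}

#' Drop unsampled indirect increments from time-domain data
#'
#' Keeps only the quadrature row pairs whose complex-pair increment index is
#' in the schedule, in schedule order.
#'
#' @param td an `nmr_fid` on the full uniform grid
#' @param schedule an `nmr_nus_schedule`
#' @return a sparse `nmr_fid` (rows = 2 x sampled increments)
#' @export
subsample_nus <- function(td, schedule) {
  idx <- schedule$sampled_increments
  rows <- as.vector(rbind(2L * idx + 1L, 2L * idx + 2L))
  new_timedomain(td$fid[, rows, , drop = FALSE], td$meta)
}

#' Serialize a ground truth as JSON next to its fixture
#' @param truth an `nmr_truth`
#' @param path output JSON path
#' @export
write_ground_truth <- function(truth, path) {
  obj <- truth
  class(obj) <- NULL
  obj$acquisition <- unclass(obj$acquisition)
  obj$applied_phase <- lapply(obj$applied_phase, unclass)
  if (!is.null(obj$nus_schedule)) obj$nus_schedule <- unclass(obj$nus_schedule)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Seeded Poisson-gap-like NUS schedule
#'
#' Gaps between sampled increments grow towards late evolution times
#' (sinusoidal weighting), emulating the sampling class commonly used for
#' decaying signals; increment 0 is always sampled.
#'
#' @param full_size uniform grid size (complex increments)
#' @param fraction fraction of increments to sample, in (0, 1]
#' @param seed RNG seed
#' @return an `nmr_nus_schedule`
#' @export
poisson_gap_schedule <- function(full_size, fraction, seed = 1L) {
  target <- max(2L, round(full_size * fraction))
  if (target >= full_size) return(new_nus_schedule(0:(full_size - 1L), full_size))
  set.seed(seed)
  lambda <- (1 / fraction - 1) * 2
  for (try in 1:200) {
    idx <- integer(0)
    i <- 0L
    while (i < full_size) {
      idx <- c(idx, i)
      g <- stats::rpois(1L, lambda * sin((i + 0.5) / full_size * pi / 2))
      i <- i + 1L + g
    }
    if (length(idx) == target) break
    lambda <- lambda * length(idx) / target
  }
  new_nus_schedule(idx, full_size)
}
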