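# Time-domain to frequency-domain processing: solvent suppression,
# apodization, zero-filling, FFT with quadrature handling, phase correction
# and region extraction.

#' Suppress the on-carrier (solvent) signal of a direct-dimension FID
#'
#' Subtracts a centred moving average (default half-width 16 complex points,
#' window shrinking at the edges), i.e. a boxcar low-pass of the FID. The
#' zero-frequency component — the on-resonance solvent after quadrature
#' detection — is captured by the low-pass and removed; off-resonance
#' signals pass nearly unchanged.
#'
#' @param fid_row complex FID vector
#' @param half_width boxcar half-width in points
#' @return filtered complex vector
#' @export
solvent_suppress <- function(fid_row, half_width = 16L) {
  n <- length(fid_row)
  if (n < 3L) {
    warning("FID shorter than 3 points: solvent filter is a passthrough")
    return(fid_row)
  }
  cs <- cumsum(c(0, fid_row))
  i <- seq_len(n)
  lo <- pmax(1L, i - half_width); hi <- pmin(n, i + half_width)
  low <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  fid_row - low
}

#' Apodize an FID with a window function
#'
#' Sine-bell weight at point `i` of `n` (0-based):
#' `sin(pi*off + pi*(end - off)*i/(n - 1))^pow`. Exponential weight:
#' `exp(-pi*lb_hz*i*dwell)`. Gaussian weight:
#' `exp(-(pi*lb_hz*i*dwell)^2/(4*log(2)))` (Gaussian broadening of FWHM
#' `lb_hz`). The half-first-point scaling is applied at transform time by
#' the pipeline, not here.
#'
#' @param fid_row complex FID vector
#' @param window an [new_window()] specification
#' @param dwell sampling interval in seconds (1/sw); needed for time-based
#'   windows
#' @return weighted complex vector
#' @export
apodize <- function(fid_row, window, dwell = 1) {
  n <- length(fid_row)
  if (n == 0L || window$kind == "none") return(fid_row)
  i <- seq_len(n) - 1L
  w <- switch(window$kind,
    sine_bell = sin(pi * window$off +
                    pi * (window$end - window$off) * i / (n - 1))^window$pow,
    exponential = exp(-pi * window$lb_hz * i * dwell),
    gaussian = exp(-(pi * window$lb_hz * i * dwell)^2 / (4 * log(2))))
  fid_row * w
}

#' Zero-fill an FID
#'
#' Appends zeros until the length is `n * 2^folds`.
#'
#' @param fid_row complex vector
#' @param folds number of doublings (>= 0)
#' @return zero-filled vector
#' @export
zero_fill <- function(fid_row, folds) {
  if (folds < 0) nmr_stop("folds must be >= 0")
  folds <- as.integer(folds)
  if (folds == 0L) return(fid_row)
  c(fid_row, complex(length.out = length(fid_row) * (2^folds - 1L)))
}

#' Fourier transform a direct-dimension FID row
#'
#' Complex FFT followed by a reordering that places the carrier at the
#' centre and index 0 at the downfield (+sw/2) edge. A Bruker group delay is
#' compensated by a first-order phase ramp totalling `360 * group_delay`
#' degrees across the spectrum; alternatively the integer part can be
#' removed as a circular time shift with only the fractional remainder
#' phased (`method = "circular_shift"`).
#'
#' @param fid_row complex FID (after windowing/zero-filling)
#' @param group_delay group delay in points (>= 0)
#' @param method `"phase_ramp"` or `"circular_shift"`
#' @return complex spectrum row, downfield-first ordering
#' @export
transform_direct <- function(fid_row, group_delay = 0,
                             method = c("phase_ramp", "circular_shift")) {
  method <- match.arg(method)
  x <- fid_row
  gd <- group_delay
  if (gd > 0 && method == "circular_shift") {
    k <- floor(gd)
    if (k > 0) x <- c(x[-seq_len(k)], x[seq_len(k)])
    gd <- gd - k
  }
  s <- fft_to_downfield(fft(x))
  if (gd > 0) {
    n <- length(s)
    frac <- downfield_offsets_hz(n, 1)   # offset as a fraction of sw
    s <- s * exp(2i * pi * gd * frac)
  }
  s
}

#' Recombine indirect-dimension quadrature rows into complex pairs
#'
#' Input is a plane of `2 * ni` complex rows (quadrature pairs adjacent,
#' direct dimension along columns, already transformed or not). Returns the
#' hypercomplex pair of `ni x ncol` complex matrices: `c_r` built from the
#' direct-real channel and `c_i` from the direct-imaginary channel, with the
#' indirect dimension now complex. `states_tppi` additionally negates every
#' second complex point, which moves axial artifacts from the centre to the
#' spectrum edge; `echo_antiecho` first recombines row pairs as
#' `((e + a)/2, i (e - a)/2)` and then proceeds as States.
#'
#' @param plane complex matrix with an even number of rows
#' @param mode `"states"`, `"states_tppi"` or `"echo_antiecho"`
#' @return list with complex matrices `c_r` and `c_i` (`ni` rows each)
#' @export
transform_indirect <- function(plane,
                               mode = c("states", "states_tppi",
                                        "echo_antiecho")) {
  mode <- match.arg(mode)
  nr <- nrow(plane)
  if (nr %% 2L != 0L) nmr_stop("incomplete quadrature pairs: odd row count")
  ni <- nr %/% 2L
  A <- plane[seq(1L, nr, 2L), , drop = FALSE]   # cos / echo rows
  B <- plane[seq(2L, nr, 2L), , drop = FALSE]   # sin / antiecho rows
  if (mode == "echo_antiecho") {
    e <- A; a <- B
    A <- (e + a) / 2
    B <- 1i * (e - a) / 2
  }
  c_r <- Re(A) + 1i * Re(B)
  c_i <- Im(A) + 1i * Im(B)
  if (mode == "states_tppi") {
    sgn <- rep_len(c(1, -1), ni)
    c_r <- c_r * sgn
    c_i <- c_i * sgn
  }
  list(c_r = c_r, c_i = c_i)
}

#' Apply zeroth/first-order phase correction to a complex spectrum row
#'
#' `out[k] = in[k] * exp(i * (p0 + p1 * k/(N-1)) * pi/180)` with the pivot
#' at point 0 and `p1` the total sweep across the displayed spectrum.
#'
#' @param spectrum_row complex vector
#' @param phase an [new_phase()] object
#' @return phased complex vector
#' @export
apply_phase <- function(spectrum_row, phase) {
  if (!is.complex(spectrum_row))
    nmr_stop("imaginary data required: apply_phase needs a complex vector")
  n <- length(spectrum_row)
  k <- seq_len(n) - 1L
  ang <- (phase$p0_deg + phase$p1_deg * k / max(1L, n - 1L)) * pi / 180
  spectrum_row * exp(1i * ang)
}

# objective for automatic phasing: entropy of the first derivative of the
# real part plus a penalty on negative intensity, both on the normalised
# spectrum (ACME-style)
autophase_objective <- function(rows, p0, p1) {
  ph <- new_phase(p0, p1)
  total_ent <- 0; total_pen <- 0
  for (r in seq_len(nrow(rows))) {
    y <- apply_phase(rows[r, ], ph)
    re <- Re(y) / max(Mod(y))          # normalized: both terms are O(1)
    h <- abs(diff(re))
    sh <- sum(h)
    if (sh > 0) {
      p <- h / sh
      total_ent <- total_ent + sum(-p * log(p + 1e-15))
    }
    total_pen <- total_pen + sum(pmax(0, -re)^2)
  }
  (total_ent + 50 * total_pen) / nrow(rows)
}

#' Automatic zeroth/first-order phase determination
#'
#' Minimizes an objective combining the entropy of the first derivative of
#' the real part with a quadratic penalty on negative intensity, over
#' `p0 in [-180, 180) x p1 in [-360, 360]`: a coarse 10 x 30 degree grid
#' search followed by Nelder-Mead refinement. Applying the returned phases
#' yields an absorption-mode real part.
#'
#' @param x complex vector or complex matrix (one spectrum row per matrix
#'   row; the objective is averaged over rows)
#' @return an [new_phase()] object
#' @export
autophase <- function(x) {
  if (!is.complex(x)) nmr_stop("imaginary data required for autophase")
  rows <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  mag <- Mod(rows)
  if (max(mag) <= 0 ||
      max(mag) < stats::median(mag) + 5 * stats::mad(as.numeric(mag))) {
    warning("low signal: returning zero phases")
    return(new_phase(0, 0))
  }
  grid_p0 <- seq(-180, 170, by = 10)
  grid_p1 <- seq(-360, 360, by = 30)
  best <- c(0, 0); best_f <- Inf
  for (p1 in grid_p1) for (p0 in grid_p0) {
    f <- autophase_objective(rows, p0, p1)
    if (f < best_f) { best_f <- f; best <- c(p0, p1) }
  }
  opt <- optim(best, function(p) autophase_objective(rows, p[1], p[2]),
               method = "Nelder-Mead",
               control = list(maxit = 400, reltol = 1e-10))
  p0 <- ((opt$par[1] + 180) %% 360) - 180
  new_phase(p0, opt$par[2])
}

#' Extract a ppm region from a spectrum
#'
#' Slices the matrix (and any imaginary quadrants) along one dimension; the
#' axis calibration is updated so that the ppm of every retained point is
#' unchanged.
#'
#' @param spectrum an `nmr_spectrum`
#' @param dim `"direct"` or `"indirect"`
#' @param ppm_lo,ppm_hi region bounds in ppm (order-independent)
#' @return the sliced `nmr_spectrum`
#' @export
extract_region <- function(spectrum, dim = c("direct", "indirect"),
                           ppm_lo, ppm_hi) {
  dim <- match.arg(dim)
  axis <- if (dim == "direct") spectrum$axis_direct else spectrum$axis_indirect
  lo <- min(ppm_lo, ppm_hi); hi <- max(ppm_lo, ppm_hi)
  p <- axis_ppm(axis)
  keep <- which(p >= lo & p <= hi)
  if (length(keep) == 0L)
    nmr_stop("extraction range [", lo, ", ", hi, "] does not overlap the axis")
  i0 <- min(keep); i1 <- max(keep)
  slc <- function(m) {
    if (is.null(m)) return(NULL)
    if (dim == "direct") m[, , i0:i1, drop = FALSE]
    else m[, i0:i1, , drop = FALSE]
  }
  ax_new <- axis_slice(axis, i0 - 1L, i1 - 1L)
  new_spectrum(slc(spectrum$data),
               if (dim == "direct") ax_new else spectrum$axis_direct,
               if (dim == "indirect") ax_new else spectrum$axis_indirect,
               imag_direct = slc(spectrum$imag_direct),
               imag_indirect = slc(spectrum$imag_indirect),
               imag_both = slc(spectrum$imag_both),
               noise_sigma = spectrum$noise_sigma)
}

# process the direct dimension of every row of one plane; returns the complex
# row matrix after FFT (and optional phasing), plus resolved phase
process_direct_rows <- function(rows, meta, dscheme, phase_resolved = NULL) {
  sw <- meta$sw_hz[1]
  out <- NULL
  for (r in seq_len(nrow(rows))) {
    x <- rows[r, ]
    if (dscheme$solvent_filter) x <- solvent_suppress(x)
    x <- apodize(x, dscheme$window, dwell = 1 / sw)
    x[1] <- 0.5 * x[1]                     # half-first-point convention
    x <- zero_fill(x, dscheme$zero_fill_folds)
    s <- transform_direct(x, group_delay = meta$group_delay)
    if (is.null(out)) out <- matrix(0i, nrow(rows), length(s))
    out[r, ] <- s
  }
  if (is.null(phase_resolved)) {
    phase_resolved <- if (identical(dscheme$phase, "auto"))
      autophase(out[1, ]) else dscheme$phase
  }
  for (r in seq_len(nrow(out))) out[r, ] <- apply_phase(out[r, ], phase_resolved)
  list(rows = out, phase = phase_resolved)
}

# indirect-dimension processing of hypercomplex pair matrices
process_indirect_cols <- function(cc, meta, ischeme, phase_resolved = NULL) {
  sw1 <- meta$sw_hz[2]
  proc_one <- function(m) {
    res <- NULL
    for (j in seq_len(ncol(m))) {
      x <- m[, j]
      x <- apodize(x, ischeme$window, dwell = 1 / sw1)
      x[1] <- 0.5 * x[1]
      x <- zero_fill(x, ischeme$zero_fill_folds)
      s <- transform_direct(x)             # plain FFT + downfield ordering
      if (is.null(res)) res <- matrix(0i, length(s), ncol(m))
      res[, j] <- s
    }
    res
  }
  Fr <- proc_one(cc$c_r)
  Fi <- proc_one(cc$c_i)
  if (is.null(phase_resolved)) {
    phase_resolved <- if (identical(ischeme$phase, "auto")) {
      jmax <- which.max(apply(Mod(Fr), 2, max))
      autophase(Fr[, jmax])
    } else ischeme$phase
  }
  for (j in seq_len(ncol(Fr))) {
    Fr[, j] <- apply_phase(Fr[, j], phase_resolved)
    Fi[, j] <- apply_phase(Fi[, j], phase_resolved)
  }
  list(Fr = Fr, Fi = Fi, phase = phase_resolved)
}

#' Process a 2D (or the first plane of a pseudo-3D) time-domain dataset
#'
#' Direct dimension per row: solvent filter (if enabled), apodization,
#' half-first-point scaling, zero-filling, FFT with group-delay
#' compensation, phasing (automatic or given), then ppm extraction. Indirect
#' dimension per column: quadrature recombination, apodization,
#' half-first-point scaling, zero-filling, FFT, phasing. All four
#' hypercomplex quadrants are retained unless `keep_imaginary = FALSE`.
#'
#' @param td an `nmr_fid`
#' @param meta an `nmr_acq` (defaults to `td$meta`)
#' @param scheme an [new_scheme()]
#' @param keep_imaginary retain imaginary quadrants in the output
#' @return an `nmr_spectrum` with attribute `"phases"` (resolved direct and
#'   indirect phase objects)
#' @export
process_2d <- function(td, meta = td$meta, scheme = new_scheme(),
                       keep_imaginary = TRUE) {
  np <- dim(td$fid)[1]
  planes <- if (scheme$first_plane_only) 1L else seq_len(np)
  out <- NULL
  dphase <- NULL; iphase <- NULL
  for (p in planes) {
    res <- tryCatch(
      process_one_plane(td$fid[p, , , drop = TRUE], meta, scheme,
                        dphase, iphase),
      error = function(e) nmr_stop("plane ", p, ": ", conditionMessage(e)))
    dphase <- res$dphase; iphase <- res$iphase
    if (is.null(out)) {
      d <- dim(res$spec$data)
      out <- list(data = array(0, c(length(planes), d[2], d[3])),
                  ri = array(0, c(length(planes), d[2], d[3])),
                  ir = array(0, c(length(planes), d[2], d[3])),
                  ii = array(0, c(length(planes), d[2], d[3])),
                  ax2 = res$spec$axis_direct, ax1 = res$spec$axis_indirect)
    }
    k <- match(p, planes)
    out$data[k, , ] <- res$spec$data[1, , ]
    out$ri[k, , ] <- res$spec$imag_direct[1, , ]
    out$ir[k, , ] <- res$spec$imag_indirect[1, , ]
    out$ii[k, , ] <- res$spec$imag_both[1, , ]
  }
  spec <- new_spectrum(out$data, out$ax2, out$ax1,
                       imag_direct = if (keep_imaginary) out$ri,
                       imag_indirect = if (keep_imaginary) out$ir,
                       imag_both = if (keep_imaginary) out$ii)
  attr(spec, "phases") <- list(direct = dphase, indirect = iphase)
  spec
}

process_one_plane <- function(plane, meta, scheme, dphase = NULL,
                              iphase = NULL) {
  if (is.null(dim(plane))) plane <- matrix(plane, 1L)
  dres <- process_direct_rows(plane, meta, scheme$direct, dphase)
  cc <- transform_indirect(dres$rows, meta$acquisition_mode)
  ires <- process_indirect_cols(cc, meta, scheme$indirect, iphase)
  nd <- ncol(ires$Fr); ni <- nrow(ires$Fr)
  ax2 <- axis_from_carrier(nd, meta$sw_hz[1], meta$obs_mhz[1],
                           meta$carrier_ppm[1])
  ax1 <- axis_from_carrier(ni, meta$sw_hz[2], meta$obs_mhz[2],
                           meta$carrier_ppm[2])
  spec <- new_spectrum(Re(ires$Fr), ax2, ax1,
                       imag_direct = Re(ires$Fi),
                       imag_indirect = Im(ires$Fr),
                       imag_both = Im(ires$Fi))
  if (!is.null(scheme$direct$extract_ppm))
    spec <- extract_region(spec, "direct", scheme$direct$extract_ppm[1],
                           scheme$direct$extract_ppm[2])
  if (!is.null(scheme$indirect$extract_ppm))
    spec <- extract_region(spec, "indirect", scheme$indirect$extract_ppm[1],
                           scheme$indirect$extract_ppm[2])
  list(spec = spec, dphase = dres$phase, iphase = ires$phase)
}

#' Process every plane of a pseudo-3D dataset with one scheme
#'
#' All planes are processed sequentially with identical parameters
#' (automatic phases are resolved on the first plane and reused); plane
#' order is preserved. Requires `first_plane_only = FALSE`.
#'
#' @inheritParams process_2d
#' @return a multi-plane `nmr_spectrum`
#' @export
process_pseudo3d <- function(td, meta = td$meta, scheme = new_scheme()) {
  if (dim(td$fid)[1] < 2L) nmr_stop("pseudo-3D processing requires >= 2 planes")
  if (scheme$first_plane_only)
    nmr_stop("first_plane_only must be FALSE for pseudo-3D processing")
  process_2d(td, meta, scheme)
}
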