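# Independent oracles, written against the format documentation and basic
# definitions -- deliberately NOT sharing code with the package internals.

# --- independent ft2 header parser (readBin at documented word offsets) ----
oracle_ft2_header <- function(path) {
  hdr <- readBin(path, "numeric", n = 512L, size = 4L, endian = "little")
  list(fltorder = hdr[3], dimcount = hdr[10],
       size = hdr[100], specnum = hdr[220],
       f2sw = hdr[101], f2orig = hdr[102], f2obs = hdr[120],
       f1sw = hdr[230], f1orig = hdr[250], f1obs = hdr[219],
       f3size = hdr[16], quadflag = hdr[107])
}

# --- independent ucsf reader: header fields + full tile reassembly --------
oracle_ucsf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 10L)
  ndim <- as.integer(readBin(con, "raw", n = 1L))
  invisible(readBin(con, "raw", n = 180L - 11L))
  rd_axis <- function() {
    nuc <- readBin(con, "raw", n = 8L)
    npts <- readBin(con, "integer", size = 4L, endian = "big")
    invisible(readBin(con, "integer", size = 4L, endian = "big"))
    tile <- readBin(con, "integer", size = 4L, endian = "big")
    fl <- readBin(con, "numeric", n = 3L, size = 4L, endian = "big")
    invisible(readBin(con, "raw", n = 128L - 32L))
    list(n = npts, tile = tile, obs = fl[1], sw = fl[2], center = fl[3])
  }
  a1 <- rd_axis(); a2 <- rd_axis()
  nt1 <- ceiling(a1$n / a1$tile); nt2 <- ceiling(a2$n / a2$tile)
  big <- matrix(0, nt1 * a1$tile, nt2 * a2$tile)
  for (bi in seq_len(nt1)) for (bj in seq_len(nt2)) {
    tl <- readBin(con, "numeric", n = a1$tile * a2$tile, size = 4L,
                  endian = "big")
    big[(bi - 1L) * a1$tile + seq_len(a1$tile),
        (bj - 1L) * a2$tile + seq_len(a2$tile)] <-
      matrix(tl, a1$tile, a2$tile, byrow = TRUE)
  }
  list(magic = rawToChar(magic[1:8]), ndim = ndim, a1 = a1, a2 = a2,
       matrix = big[seq_len(a1$n), seq_len(a2$n), drop = FALSE])
}

# --- independent Bruker ser decoder (struct-level) -------------------------
oracle_bruker_ser <- function(path, td2, data_type, endian) {
  sz <- if (data_type == "int32") 4L else 8L
  rec_bytes <- if (data_type == "int32") ceiling(td2 * 4 / 1024) * 1024
               else td2 * 8
  fsize <- file.size(path)
  n_rows <- fsize / rec_bytes
  con <- file(path, "rb")
  on.exit(close(con))
  rows <- vector("list", n_rows)
  for (r in seq_len(n_rows)) {
    v <- if (data_type == "int32")
      readBin(con, "integer", n = rec_bytes / 4L, size = 4L, endian = endian)
    else readBin(con, "numeric", n = rec_bytes / 8L, size = 8L, endian = endian)
    v <- v[seq_len(td2)]
    rows[[r]] <- complex(real = v[c(TRUE, FALSE)], imaginary = v[c(FALSE, TRUE)])
  }
  do.call(rbind, rows)
}

# --- direct 2D FFT oracle for the full pipeline ----------------------------
# Reference processing with windows "none": half-first-point scaling, FFT
# along both dimensions, downfield reordering, States recombination and
# explicit phases -- implemented straight from the conventions, not via the
# package pipeline.
oracle_fft2d <- function(fid_plane, p0d = 0, p1d = 0, p0i = 0, p1i = 0) {
  reorder <- function(x) {
    n <- length(x)
    x[(((n %/% 2L) - seq_len(n) + 1L) %% n) + 1L]
  }
  phase <- function(v, p0, p1) {
    k <- seq_along(v) - 1L
    v * exp(1i * (p0 + p1 * k / (length(v) - 1L)) * pi / 180)
  }
  nr <- nrow(fid_plane)
  rows <- fid_plane
  rows[, 1L] <- rows[, 1L] * 0.5
  F2 <- t(apply(rows, 1L, function(x) phase(reorder(fft(x)), p0d, p1d)))
  ni <- nr %/% 2L
  A <- F2[seq(1L, nr, 2L), , drop = FALSE]
  B <- F2[seq(2L, nr, 2L), , drop = FALSE]
  c_r <- Re(A) + 1i * Re(B)
  c_i <- Im(A) + 1i * Im(B)
  do_cols <- function(M) {
    M[1L, ] <- M[1L, ] * 0.5
    apply(M, 2L, function(x) phase(reorder(fft(x)), p0i, p1i))
  }
  list(rr = Re(do_cols(c_r)), ri = Re(do_cols(c_i)),
       ir = Im(do_cols(c_r)), ii = Im(do_cols(c_i)))
}

# --- numerical Gaussian (x) Lorentzian convolution -------------------------
oracle_voigt_conv <- function(dx, sigma, gamma) {
  f <- function(u) {
    exp(-u^2 / (2 * sigma^2)) / (sigma * sqrt(2 * pi)) *
      gamma / (pi * ((dx - u)^2 + gamma^2))
  }
  integrate(f, -Inf, Inf, rel.tol = 1e-12, abs.tol = 1e-13)$value
}

# --- shoelace area of a closed polyline ------------------------------------
oracle_polygon_area <- function(pts) {
  x <- pts[, 1L]; y <- pts[, 2L]
  n <- nrow(pts)
  abs(sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y)) / 2
}

# --- fixture builders ------------------------------------------------------
hsqc_acq <- function(nd = 128L, ni = 32L, ...) {
  new_acquisition_meta(n_complex_points = c(nd, ni), sw_hz = c(8000, 2000),
                       obs_mhz = c(600.13, 60.81), carrier_ppm = c(4.7, 118),
                       ...)
}

# peaks spread over the window so p0/p1 are jointly identifiable
spread_peaks <- function(n = 5L) {
  data.frame(
    x_ppm = seq(0.9, 8.9, length.out = n),
    y_ppm = seq(105, 130, length.out = n),
    amplitude = c(10, 7, 5, 8, 6, 9, 4, 6)[seq_len(n)],
    r2_x_hz = 18, r2_y_hz = 8)
}

scheme_known <- function(...) {
  new_scheme(direct_phase = new_phase(0, 0),
             indirect_phase = new_phase(0, 0), ...)
}

# subpixel position of the global maximum of a matrix (row, col), 0-based
refined_max <- function(m) {
  ij <- which(m == max(m), arr.ind = TRUE)[1L, ]
  para <- function(fm, f0, fp) {
    den <- fm - 2 * f0 + fp
    if (abs(den) > 0) 0.5 * (fm - fp) / den else 0
  }
  ij <- unname(ij)
  c(row = ij[1L] - 1L + para(m[ij[1L] - 1L, ij[2L]], m[ij[1L], ij[2L]],
                             m[ij[1L] + 1L, ij[2L]]),
    col = ij[2L] - 1L + para(m[ij[1L], ij[2L] - 1L], m[ij[1L], ij[2L]],
                             m[ij[1L], ij[2L] + 1L]))
}

# spectral noise sigma produced by unit time-domain noise, for SNR targeting
snr_calibration <- local({
  cache <- new.env(parent = emptyenv())
  function(acq, scheme) {
    key <- paste(acq$n_complex_points, collapse = "x")
    if (!is.null(cache[[key]])) return(cache[[key]])
    tr <- new_ground_truth(data.frame(x_ppm = numeric(), y_ppm = numeric(),
                                      amplitude = numeric(),
                                      r2_x_hz = numeric(), r2_y_hz = numeric()),
                           acquisition = acq, noise_sigma = 1, seed = 999L)
    sp <- process_2d(generate_fid(tr), scheme = scheme)
    cache[[key]] <- stats::sd(as.numeric(sp$data))
    cache[[key]]
  }
})
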