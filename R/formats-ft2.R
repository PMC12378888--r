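# NMRPipe-style ft2 files: a 512-float32 header followed by float32 data.
# Header words used here (0-based float indices, the ecosystem's FDATA map):
FD <- list(
  MAGIC = 0L, FLTFORMAT = 1L, FLTORDER = 2L, DIMCOUNT = 9L,
  F3SIZE = 15L, F4SIZE = 32L, DIMORDER1 = 24L,
  F1QUADFLAG = 55L, F2QUADFLAG = 56L, PIPEFLAG = 57L,
  F2CAR = 66L, F1CAR = 67L, QUADFLAG = 106L,
  SIZE = 99L, F2SW = 100L, F2ORIG = 101L, F2OBS = 119L,
  NOISE = 153L, F1OBS = 218L, SPECNUM = 219L, F2FTFLAG = 220L,
  TRANSPOSED = 221L, F1FTFLAG = 222L, F1SW = 229L, F1ORIG = 249L,
  PHASE2D = 256L, F3OBS = 10L, FILECOUNT = 442L
)
FD_FLTORDER <- 2.345

# the literal float whose bytes are ee ee ff ff, the format sentinel
fd_fltformat_value <- function() {
  readBin(as.raw(c(0xff, 0xff, 0xee, 0xee)), "numeric", size = 4L,
          endian = "little")
}

#' Write a spectrum as an ft2 file
#'
#' Data are stored plane after plane as float32. When the spectrum carries
#' hypercomplex imaginary parts, each stored row holds the real points
#' followed by the direct-dimension imaginary points, and rows alternate
#' indirect-real / indirect-imaginary (the four-quadrant layout). Pseudo-3D
#' stacks set the third-dimension size word; axis calibration goes into the
#' sw/obs/origin header words.
#'
#' @param spectrum an `nmr_spectrum`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_ft2 <- function(spectrum, path) {
  hdr <- numeric(512)
  hdr[FD$FLTFORMAT + 1L] <- fd_fltformat_value()
  hdr[FD$FLTORDER + 1L] <- FD_FLTORDER
  hdr[FD$DIMCOUNT + 1L] <- 2
  hdr[FD$DIMORDER1 + 1L + 0:3] <- c(2, 1, 3, 4)
  np <- n_planes(spectrum)
  d <- dim(spectrum$data)
  has_ri <- !is.null(spectrum$imag_direct)
  has_ir <- !is.null(spectrum$imag_indirect)
  hdr[FD$SIZE + 1L] <- d[3]
  hdr[FD$SPECNUM + 1L] <- if (has_ir) 2L * d[2] else d[2]
  hdr[FD$F3SIZE + 1L] <- np
  hdr[FD$F4SIZE + 1L] <- 1
  hdr[FD$FILECOUNT + 1L] <- 1
  hdr[FD$QUADFLAG + 1L] <- if (has_ri || has_ir) 0 else 1
  hdr[FD$F2QUADFLAG + 1L] <- if (has_ri) 0 else 1
  hdr[FD$F1QUADFLAG + 1L] <- if (has_ir) 0 else 1
  hdr[FD$F2FTFLAG + 1L] <- 1
  hdr[FD$F1FTFLAG + 1L] <- 1
  hdr[FD$PHASE2D + 1L] <- 2
  ax2 <- spectrum$axis_direct; ax1 <- spectrum$axis_indirect
  hdr[FD$F2SW + 1L] <- ax2$sw_hz;  hdr[FD$F2OBS + 1L] <- ax2$obs_mhz
  hdr[FD$F2ORIG + 1L] <- ax2$origin_hz
  hdr[FD$F2CAR + 1L] <- axis_carrier_ppm(ax2)
  hdr[FD$F1SW + 1L] <- ax1$sw_hz;  hdr[FD$F1OBS + 1L] <- ax1$obs_mhz
  hdr[FD$F1ORIG + 1L] <- ax1$origin_hz
  hdr[FD$F1CAR + 1L] <- axis_carrier_ppm(ax1)
  if (!is.null(spectrum$noise_sigma)) hdr[FD$NOISE + 1L] <- spectrum$noise_sigma

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con, size = 4L, endian = "little")
  for (p in seq_len(np)) {
    rr <- plane_matrix(spectrum, p)
    if (d[2] == 1L) rr <- matrix(rr, 1L)
    rows <- vector("list", hdr[FD$SPECNUM + 1L])
    for (i in seq_len(d[2])) {
      row_r <- rr[i, ]
      if (has_ri) row_r <- c(row_r, spectrum$imag_direct[p, i, ])
      if (has_ir) {
        row_i <- spectrum$imag_indirect[p, i, ]
        if (has_ri) row_i <- c(row_i, spectrum$imag_both[p, i, ])
        rows[[2L * i - 1L]] <- row_r
        rows[[2L * i]] <- row_i
      } else rows[[i]] <- row_r
    }
    writeBin(unlist(rows), con, size = 4L, endian = "little")
  }
  invisible(path)
}

#' Read an ft2 file
#'
#' @param path path to an ft2 file written by this package or a compatible
#'   tool (2D, optionally hypercomplex, optionally multi-plane)
#' @return an `nmr_spectrum`
#' @export
read_ft2 <- function(path) {
  raw_all <- readBin(path, "raw", n = file.size(path))
  if (length(raw_all) < 2048L) nmr_stop("not an ft2 file: shorter than 512 floats")
  endian <- "little"
  hdr <- readBin(raw_all, "numeric", n = 512L, size = 4L, endian = endian)
  if (abs(hdr[FD$FLTORDER + 1L] - FD_FLTORDER) > 1e-4) {
    endian <- "big"
    hdr <- readBin(raw_all, "numeric", n = 512L, size = 4L, endian = endian)
    if (abs(hdr[FD$FLTORDER + 1L] - FD_FLTORDER) > 1e-4)
      nmr_stop("not an ft2 file: bad float-order word")
  }
  nd <- as.integer(round(hdr[FD$SIZE + 1L]))
  nrows <- as.integer(round(hdr[FD$SPECNUM + 1L]))
  np <- max(1L, as.integer(round(hdr[FD$F3SIZE + 1L])))
  has_ri <- hdr[FD$F2QUADFLAG + 1L] == 0
  has_ir <- hdr[FD$F1QUADFLAG + 1L] == 0
  ni <- if (has_ir) nrows %/% 2L else nrows
  row_len <- if (has_ri) 2L * nd else nd
  need <- 512L + np * nrows * row_len
  vals <- readBin(raw_all[-(1:2048)], "numeric",
                  n = length(raw_all) %/% 4L - 512L, size = 4L, endian = endian)
  if (length(vals) < np * nrows * row_len)
    nmr_stop("ft2 data shorter than header declares")
  data <- array(0, c(np, ni, nd))
  ri <- if (has_ri) array(0, c(np, ni, nd)) else NULL
  ir <- if (has_ir) array(0, c(np, ni, nd)) else NULL
  ii <- if (has_ri && has_ir) array(0, c(np, ni, nd)) else NULL
  pos <- 0L
  for (p in seq_len(np)) for (i in seq_len(ni)) {
    row <- vals[pos + seq_len(row_len)]; pos <- pos + row_len
    data[p, i, ] <- row[seq_len(nd)]
    if (has_ri) ri[p, i, ] <- row[nd + seq_len(nd)]
    if (has_ir) {
      row2 <- vals[pos + seq_len(row_len)]; pos <- pos + row_len
      ir[p, i, ] <- row2[seq_len(nd)]
      if (has_ri) ii[p, i, ] <- row2[nd + seq_len(nd)]
    }
  }
  ax2 <- new_axis(nd, hdr[FD$F2SW + 1L], hdr[FD$F2OBS + 1L], hdr[FD$F2ORIG + 1L])
  ax1 <- new_axis(ni, hdr[FD$F1SW + 1L], hdr[FD$F1OBS + 1L], hdr[FD$F1ORIG + 1L])
  noise <- hdr[FD$NOISE + 1L]
  new_spectrum(data, ax2, ax1, imag_direct = ri, imag_indirect = ir,
               imag_both = ii, noise_sigma = if (noise > 0) noise else NULL)
}
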