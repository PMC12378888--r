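# UCSF Sparky format: 180-byte file header, one 128-byte header per axis
# (w1/indirect first), then float32 data in row-major tiles. All big-endian.

UCSF_TILE <- 128L

ucsf_axis_header <- function(axis, tile, nucleus) {
  con <- rawConnection(raw(0), "r+")
  on.exit(close(con))
  nuc <- charToRaw(substr(nucleus, 1L, 5L))
  writeBin(c(nuc, raw(8L - length(nuc))), con)            # bytes 0-7
  writeBin(as.integer(axis$n_points), con, size = 4L, endian = "big")
  writeBin(0L, con, size = 4L, endian = "big")            # spare
  writeBin(as.integer(tile), con, size = 4L, endian = "big")
  # centre ppm = shift of point n/2; stored at float32 precision like all
  # header words, which bounds the round-trip ppm fidelity
  writeBin(c(axis$obs_mhz, axis$sw_hz, axis_carrier_ppm(axis)), con,
           size = 4L, endian = "big")
  hdr <- rawConnection_value(con)
  c(hdr, raw(128L - length(hdr)))
}

rawConnection_value <- function(con) {
  seek(con, 0L)
  readBin(con, "raw", n = 1e6)
}

#' Write a spectrum as a UCSF Sparky file
#'
#' Sparky files hold real data only: imaginary quadrants are dropped with a
#' warning. Data are tiled (128 x 128 by default, shrunk for small matrices)
#' with edge tiles zero-padded, as the format requires.
#'
#' @param spectrum an `nmr_spectrum` (single plane)
#' @param path output file path
#' @param tile tile edge length in points
#' @return `path`, invisibly
#' @export
write_ucsf <- function(spectrum, path, tile = UCSF_TILE) {
  if (n_planes(spectrum) > 1L)
    nmr_stop("only 2D supported: ucsf files hold a single plane")
  if (has_imaginary(spectrum) || !is.null(spectrum$imag_indirect))
    warning("ucsf stores real data only; imaginary parts dropped")
  m <- plane_matrix(spectrum, 1L)
  ni <- nrow(m); nd <- ncol(m)
  t1 <- min(tile, ni); t2 <- min(tile, nd)
  con <- file(path, "wb")
  on.exit(close(con))
  magic <- charToRaw("UCSF NMR")
  writeBin(c(magic, raw(10L - length(magic))), con)
  writeBin(as.raw(c(2L, 1L, 0L, 2L)), con)   # ndim, ncomp, pad, version
  writeBin(raw(180L - 14L), con)
  writeBin(ucsf_axis_header(spectrum$axis_indirect, t1, "15N"), con)
  writeBin(ucsf_axis_header(spectrum$axis_direct, t2, "1H"), con)
  nt1 <- ceiling(ni / t1); nt2 <- ceiling(nd / t2)
  pad <- matrix(0, nt1 * t1, nt2 * t2)
  pad[seq_len(ni), seq_len(nd)] <- m
  for (bi in seq_len(nt1)) for (bj in seq_len(nt2)) {
    blk <- pad[(bi - 1L) * t1 + seq_len(t1), (bj - 1L) * t2 + seq_len(t2),
               drop = FALSE]
    writeBin(as.numeric(t(blk)), con, size = 4L, endian = "big")
  }
  invisible(path)
}

#' Read a UCSF Sparky file
#'
#' @param path path to a 2D ucsf file
#' @return an `nmr_spectrum` (real data only)
#' @export
read_ucsf <- function(path) {
  raw_all <- readBin(path, "raw", n = file.size(path))
  if (length(raw_all) < 180L || !identical(raw_all[1:8], charToRaw("UCSF NMR")))
    nmr_stop("not a ucsf file: bad magic string")
  ndim <- as.integer(raw_all[11L])
  if (ndim != 2L) nmr_stop("only 2D supported: file declares ", ndim, " dimensions")
  parse_axis <- function(off) {
    npt <- readBin(raw_all[off + 9:12], "integer", size = 4L, endian = "big")
    tl <- readBin(raw_all[off + 17:20], "integer", size = 4L, endian = "big")
    fl <- readBin(raw_all[off + 21:32], "numeric", n = 3L, size = 4L,
                  endian = "big")
    list(n = npt, tile = tl, obs = fl[1], sw = fl[2], car = fl[3])
  }
  a1 <- parse_axis(180L)   # indirect (w1)
  a2 <- parse_axis(308L)   # direct (w2)
  nt1 <- ceiling(a1$n / a1$tile); nt2 <- ceiling(a2$n / a2$tile)
  nfl <- nt1 * nt2 * a1$tile * a2$tile
  vals <- readBin(raw_all[-(1:436)], "numeric", n = nfl, size = 4L,
                  endian = "big")
  if (length(vals) < nfl) nmr_stop("ucsf data shorter than header declares")
  pad <- matrix(0, nt1 * a1$tile, nt2 * a2$tile)
  pos <- 0L
  for (bi in seq_len(nt1)) for (bj in seq_len(nt2)) {
    blk <- matrix(vals[pos + seq_len(a1$tile * a2$tile)], a1$tile, a2$tile,
                  byrow = TRUE)
    pos <- pos + a1$tile * a2$tile
    pad[(bi - 1L) * a1$tile + seq_len(a1$tile),
        (bj - 1L) * a2$tile + seq_len(a2$tile)] <- blk
  }
  m <- pad[seq_len(a1$n), seq_len(a2$n), drop = FALSE]
  mk_axis <- function(a) {
    origin <- a$car * a$obs - (a$n / 2 - 1) * a$sw / a$n
    new_axis(a$n, a$sw, a$obs, origin)
  }
  new_spectrum(m, mk_axis(a2), mk_axis(a1))
}
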