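# TopSpin "totxt" export: '#'-prefixed header lines declaring the ppm ranges
# and matrix size, then one intensity per line with "# row = n" separators.

#' Read a TopSpin totxt export
#'
#' The accepted dialect declares `F1LEFT`/`F1RIGHT` and `F2LEFT`/`F2RIGHT`
#' (ppm, F1 = indirect rows, F2 = direct columns) and `NROWS`/`NCOLS` on
#' comment lines; anything else is rejected as unrecognized. totxt files
#' carry no spectrometer frequency, so the axes use a nominal observe
#' frequency of 1 MHz (the ppm map is exact; Hz values are nominal).
#'
#' @param path path to the text export
#' @return an `nmr_spectrum`
#' @export
read_topspin_txt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) nmr_stop("unrecognized totxt dialect: empty file")
  hdr <- lines[startsWith(lines, "#")]
  grab <- function(key) {
    m <- regmatches(hdr, regexec(paste0(key, "\\s*=\\s*(-?[0-9.eE+]+)"), hdr))
    v <- unlist(lapply(m, function(x) if (length(x) == 2L) x[2] else NULL))
    if (length(v) == 0L)
      nmr_stop("unrecognized totxt dialect: missing ", key, " header")
    as.numeric(v[1])
  }
  f1l <- grab("F1LEFT"); f1r <- grab("F1RIGHT")
  f2l <- grab("F2LEFT"); f2r <- grab("F2RIGHT")
  nr <- as.integer(grab("NROWS")); nc <- as.integer(grab("NCOLS"))
  vals <- suppressWarnings(as.numeric(lines[!startsWith(lines, "#")]))
  vals <- vals[!is.na(vals)]
  if (length(vals) != nr * nc)
    nmr_stop("totxt value count ", length(vals), " != NROWS x NCOLS")
  m <- matrix(vals, nr, nc, byrow = TRUE)
  mk_axis <- function(left, right, n) {
    step <- (left - right) / (n - 1)         # ppm per point, downfield first
    new_axis(n, step * n, 1, right)          # obs = 1 MHz: ppm == Hz
  }
  new_spectrum(m, mk_axis(f2l, f2r, nc), mk_axis(f1l, f1r, nr))
}

#' Write a spectrum in the totxt text dialect read by [read_topspin_txt()]
#'
#' Used for fixtures and format interchange; values are printed with 9
#' significant digits.
#'
#' @param spectrum an `nmr_spectrum` (first plane written)
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_topspin_txt <- function(spectrum, path) {
  m <- plane_matrix(spectrum, 1L)
  p1 <- axis_ppm(spectrum$axis_indirect); p2 <- axis_ppm(spectrum$axis_direct)
  lines <- c("# File created by nmrdesk (totxt dialect)",
             sprintf("# F1LEFT = %.10g ppm. F1RIGHT = %.10g ppm.",
                     p1[1], p1[length(p1)]),
             sprintf("# F2LEFT = %.10g ppm. F2RIGHT = %.10g ppm.",
                     p2[1], p2[length(p2)]),
             sprintf("# NROWS = %d ( = number of points along the F1 axis)",
                     nrow(m)),
             sprintf("# NCOLS = %d ( = number of points along the F2 axis)",
                     ncol(m)))
  for (i in seq_len(nrow(m)))
    lines <- c(lines, sprintf("# row = %d", i - 1L),
               sprintf("%.9g", m[i, ]))
  writeLines(lines, path)
  invisible(path)
}
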