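#' Construct a peak list
#'
#' A peak list is a data frame with class `nmr_peaks`. Canonical columns:
#' `index`, `x_ppm`, `y_ppm`, `height`, `sigma_x`, `sigma_y`, `gamma_x`,
#' `gamma_y` (widths in points), `label`, plus optional per-plane height
#' columns `Z_A0`, `Z_A1`, ... for pseudo-3D results.
#'
#' @param x_ppm,y_ppm peak positions (ppm; x = direct, y = indirect)
#' @param height peak heights (amplitude at the peak centre)
#' @param sigma_x,sigma_y Gaussian widths in points
#' @param gamma_x,gamma_y Lorentzian HWHM widths in points
#' @param label assignment labels
#' @param plane_heights optional matrix `[peak, plane]` of per-plane heights
#' @return an `nmr_peaks` data frame
#' @export
new_peaklist <- function(x_ppm = numeric(), y_ppm = numeric(),
                         height = rep(NA_real_, length(x_ppm)),
                         sigma_x = rep(0, length(x_ppm)),
                         sigma_y = rep(0, length(x_ppm)),
                         gamma_x = rep(0, length(x_ppm)),
                         gamma_y = rep(0, length(x_ppm)),
                         label = sprintf("P%d", seq_along(x_ppm)),
                         plane_heights = NULL) {
  df <- data.frame(index = seq_along(x_ppm), x_ppm = x_ppm, y_ppm = y_ppm,
                   height = height, sigma_x = sigma_x, sigma_y = sigma_y,
                   gamma_x = gamma_x, gamma_y = gamma_y, label = label,
                   stringsAsFactors = FALSE)
  if (!is.null(plane_heights)) {
    plane_heights <- as.matrix(plane_heights)
    if (nrow(plane_heights) != nrow(df) && nrow(df) > 0L)
      nmr_stop("plane_heights must have one row per peak")
    for (j in seq_len(ncol(plane_heights)))
      df[[sprintf("Z_A%d", j - 1L)]] <- plane_heights[, j]
  }
  class(df) <- c("nmr_peaks", "data.frame")
  df
}

za_columns <- function(peaks) {
  nm <- names(peaks)
  nm[grepl("^Z_A[0-9]+$", nm)][order(as.integer(sub("^Z_A", "",
    nm[grepl("^Z_A[0-9]+$", nm)])))]
}

#' Write a peak list
#'
#' `nmrpipe_tab` emits a VARS/FORMAT header with `X_PPM`, `Y_PPM`, `HEIGHT`,
#' the lineshape width columns and, for pseudo-3D lists, `Z_A0`, `Z_A1`, ...
#' columns of relative plane heights. `sparky_list` emits
#' `Assignment w1 w2 Height` (w1 = indirect, w2 = direct); Sparky lists have
#' no plane-height columns, so those are dropped with a warning. Shifts are
#' written with 4 decimals, heights with 6 significant digits.
#'
#' @param peaks an `nmr_peaks`
#' @param path output file path
#' @param dialect `"nmrpipe_tab"` or `"sparky_list"`
#' @return `path`, invisibly
#' @export
write_peaklist <- function(peaks, path, dialect = c("nmrpipe_tab", "sparky_list")) {
  dialect <- match.arg(dialect)
  if (dialect == "sparky_list") {
    if (length(za_columns(peaks)) > 0L)
      warning("sparky_list has no plane-height columns; Z_A heights dropped")
    lines <- c(sprintf("%17s %8s %8s %14s", "Assignment", "w1", "w2", "Height"),
               sprintf("%17s %8.4f %8.4f %14.6e",
                       peaks$label, peaks$y_ppm, peaks$x_ppm, peaks$height))
    writeLines(lines, path)
    return(invisible(path))
  }
  za <- za_columns(peaks)
  vars <- c("INDEX", "X_PPM", "Y_PPM", "HEIGHT", "SIGMAX", "SIGMAY",
            "GAMMAX", "GAMMAY", "ASS", za)
  fmts <- c("%5d", "%9.4f", "%9.4f", "%+e", "%8.4f", "%8.4f", "%8.4f",
            "%8.4f", "%s", rep("%+e", length(za)))
  rows <- character(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    vals <- c(sprintf("%5d", peaks$index[i]),
              sprintf("%9.4f", peaks$x_ppm[i]), sprintf("%9.4f", peaks$y_ppm[i]),
              sprintf("%.6e", peaks$height[i]),
              sprintf("%8.4f", peaks$sigma_x[i]), sprintf("%8.4f", peaks$sigma_y[i]),
              sprintf("%8.4f", peaks$gamma_x[i]), sprintf("%8.4f", peaks$gamma_y[i]),
              peaks$label[i],
              vapply(za, function(z) sprintf("%.6e", peaks[[z]][i]), ""))
    rows[i] <- paste(vals, collapse = " ")
  }
  writeLines(c(paste(c("VARS  ", vars), collapse = " "),
               paste(c("FORMAT", fmts), collapse = " "),
               rows), path)
  invisible(path)
}

#' Read a peak list
#'
#' The nmrpipe_tab reader parses columns by VARS name, not by position, so
#' reordered columns are handled. Unknown column sets raise an error.
#'
#' @param path input file path
#' @param dialect `"nmrpipe_tab"` or `"sparky_list"`
#' @return an `nmr_peaks`
#' @export
read_peaklist <- function(path, dialect = c("nmrpipe_tab", "sparky_list")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (dialect == "sparky_list") {
    hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
    if (!identical(tolower(hdr[1]), "assignment"))
      nmr_stop("unrecognized peak list: sparky header missing Assignment")
    has_h <- any(tolower(hdr) %in% c("height", "data"))
    rec <- strsplit(trimws(lines[-1]), "\\s+")
    lab <- vapply(rec, `[`, "", 1L)
    w1 <- as.numeric(vapply(rec, `[`, "", 2L))
    w2 <- as.numeric(vapply(rec, `[`, "", 3L))
    h <- if (has_h) as.numeric(vapply(rec, function(r) r[4] %||% NA_character_, ""))
         else rep(NA_real_, length(lab))
    return(new_peaklist(x_ppm = w2, y_ppm = w1, height = h, label = lab))
  }
  vline <- grep("^VARS", lines, value = TRUE)
  if (length(vline) == 0L) nmr_stop("unrecognized peak list: no VARS header")
  vars <- strsplit(trimws(vline[1]), "\\s+")[[1]][-1]
  if (!all(c("X_PPM", "Y_PPM") %in% vars))
    nmr_stop("unrecognized peak list: X_PPM/Y_PPM columns required")
  body <- lines[!grepl("^(VARS|FORMAT|#)", lines)]
  rec <- strsplit(trimws(body), "\\s+")
  rec <- rec[lengths(rec) == length(vars)]
  col <- function(nm, num = TRUE) {
    if (!nm %in% vars) return(NULL)
    v <- vapply(rec, `[`, "", match(nm, vars))
    if (num) as.numeric(v) else v
  }
  n <- length(rec)
  za <- vars[grepl("^Z_A[0-9]+$", vars)]
  ph <- if (length(za))
    do.call(cbind, lapply(za[order(as.integer(sub("Z_A", "", za)))], col))
  else NULL
  pk <- new_peaklist(
    x_ppm = col("X_PPM"), y_ppm = col("Y_PPM"),
    height = col("HEIGHT") %||% rep(NA_real_, n),
    sigma_x = col("SIGMAX") %||% rep(0, n),
    sigma_y = col("SIGMAY") %||% rep(0, n),
    gamma_x = col("GAMMAX") %||% rep(0, n),
    gamma_y = col("GAMMAY") %||% rep(0, n),
    label = col("ASS", num = FALSE) %||% sprintf("P%d", seq_len(n)),
    plane_heights = ph)
  pk
}

#' Read a NUS sampling schedule ("nuslist") file
#'
#' One sampled complex-pair increment index per line (0-based); an optional
#' second column is ignored. The schedule is returned sorted and
#' de-duplicated.
#'
#' @param path path to the nuslist file
#' @param full_size full length of the uniform indirect grid (complex pairs)
#' @return an object of class `nmr_nus_schedule` with fields
#'   `sampled_increments`, `full_size` and `complete`
#' @export
read_nuslist <- function(path, full_size) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines[nzchar(trimws(lines))])
  idx <- suppressWarnings(as.integer(vapply(strsplit(lines, "\\s+"), `[`, "", 1L)))
  if (any(is.na(idx))) nmr_stop("nuslist contains non-integer entries")
  new_nus_schedule(idx, full_size)
}

#' Construct a NUS schedule
#' @param sampled_increments 0-based sampled indices (deduplicated, sorted)
#' @param full_size full uniform grid size
#' @export
new_nus_schedule <- function(sampled_increments, full_size) {
  idx <- sort(unique(as.integer(sampled_increments)))
  if (any(idx < 0)) nmr_stop("schedule indices must be >= 0")
  if (any(idx >= full_size))
    nmr_stop("schedule exceeds declared grid: index ", max(idx),
             " >= full_size ", full_size)
  if (!(0L %in% idx)) nmr_stop("schedule must sample increment 0")
  structure(list(sampled_increments = idx, full_size = as.integer(full_size),
                 complete = length(idx) == full_size),
            class = "nmr_nus_schedule")
}
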