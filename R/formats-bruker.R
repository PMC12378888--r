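# Bruker time-domain directories: a ser (or fid) binary plus JCAMP-DX
# parameter files acqus (direct dim) and acqu2s (indirect dim).

# minimal JCAMP-DX key=value parser; only ##$KEY= scalar lines are needed
parse_jcamp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^##\\$?([A-Za-z_0-9]+)=\\s*(.*)$", ln))[[1]]
    if (length(m) == 3L) {
      val <- trimws(m[3])
      num <- suppressWarnings(as.numeric(val))
      out[[m[2]]] <- if (!is.na(num)) num else val
    }
  }
  out
}

write_jcamp <- function(params, path, title) {
  lines <- c(sprintf("##TITLE= %s", title), "##JCAMPDX= 5.0",
             "##DATATYPE= Parameter Values")
  for (k in names(params))
    lines <- c(lines, sprintf("##$%s= %s", k, format(params[[k]], digits = 15)))
  lines <- c(lines, "##END=")
  writeLines(lines, path)
}

bruker_fnmode <- c(states = 5, states_tppi = 6, echo_antiecho = 6)
# TopSpin FnMODE codes: 4 = States, 5 = States-TPPI, 6 = Echo-Antiecho
fnmode_to_mode <- function(code) {
  switch(as.character(as.integer(code)),
         "4" = "states", "5" = "states_tppi", "6" = "echo_antiecho",
         "states")
}
mode_to_fnmode <- function(mode) {
  switch(mode, states = 4L, states_tppi = 5L, echo_antiecho = 6L)
}

# bytes occupied on disk by one FID record
bruker_record_bytes <- function(td_real, data_type, padded) {
  bytes <- td_real * if (data_type == "int32") 4L else 8L
  if (padded) as.integer(ceiling(bytes / 1024) * 1024) else as.integer(bytes)
}

#' Read a Bruker time-domain directory
#'
#' Requires `ser` (or `fid`) and `acqus`; `acqu2s` is required for 2D and
#' pseudo-3D data. Direct-dimension points are decoded into complex pairs;
#' the digital-filter group delay is recorded in the metadata but not yet
#' corrected. The pseudo-3D plane count is inferred from the total file size
#' divided by TD1 x TD2. TopSpin pads each int32 FID record to a 1-KiB
#' boundary; float64 (DTYPA = 2) records are unpadded.
#'
#' @param dir_path path to the dataset directory
#' @return a list with elements `td` (`nmr_fid`) and `meta` (`nmr_acq`)
#' @export
read_bruker <- function(dir_path) {
  ser_path <- file.path(dir_path, "ser")
  if (!file.exists(ser_path)) ser_path <- file.path(dir_path, "fid")
  acqus_path <- file.path(dir_path, "acqus")
  if (!file.exists(ser_path) || !file.exists(acqus_path))
    nmr_stop("not a Bruker dataset: missing ser/fid or acqus in ", dir_path)
  a1 <- parse_jcamp(acqus_path)
  acqu2s_path <- file.path(dir_path, "acqu2s")
  if (!file.exists(acqu2s_path))
    nmr_stop("not a Bruker dataset: acqu2s required for 2D/pseudo-3D data")
  a2 <- parse_jcamp(acqu2s_path)

  td2 <- as.integer(a1$TD)          # real points per FID (2 x complex)
  td1 <- as.integer(a2$TD)          # stored rows per plane
  data_type <- if ((a1$DTYPA %||% 2) == 0) "int32" else "float64"
  byte_order <- if ((a1$BYTORDA %||% 0) == 0) "little" else "big"
  endian <- byte_order

  fsize <- file.size(ser_path)
  rec <- bruker_record_bytes(td2, data_type, padded = data_type == "int32")
  if (fsize %% rec != 0 || (fsize %/% rec) %% td1 != 0) {
    rec <- bruker_record_bytes(td2, data_type, padded = data_type != "int32")
    if (fsize %% rec != 0 || (fsize %/% rec) %% td1 != 0)
      nmr_stop("truncated or inconsistent data: ser size ", fsize,
               " does not match TD1 x TD2 records")
  }
  n_rows_total <- as.integer(fsize %/% rec)
  np <- n_rows_total %/% td1

  con <- file(ser_path, "rb")
  on.exit(close(con))
  per_rec <- rec %/% (if (data_type == "int32") 4L else 8L)
  fid <- array(complex(real = 0), c(np, td1, td2 %/% 2L))
  for (r in seq_len(n_rows_total)) {
    vals <- if (data_type == "int32")
      as.numeric(readBin(con, "integer", n = per_rec, size = 4L, endian = endian))
    else readBin(con, "numeric", n = per_rec, size = 8L, endian = endian)
    vals <- vals[seq_len(td2)]
    p <- (r - 1L) %/% td1 + 1L
    i <- (r - 1L) %% td1 + 1L
    fid[p, i, ] <- complex(real = vals[c(TRUE, FALSE)],
                           imaginary = vals[c(FALSE, TRUE)])
  }
  meta <- new_acquisition_meta(
    n_complex_points = c(td2 %/% 2L, td1 %/% 2L),
    sw_hz = c(a1$SW_h, a2$SW_h),
    obs_mhz = c(a1$SFO1, a2$SFO1),
    carrier_ppm = c((a1$O1 %||% 0) / a1$SFO1, (a2$O1 %||% 0) / a2$SFO1),
    acquisition_mode = fnmode_to_mode(a2$FnMODE %||% 5),
    data_type = data_type, byte_order = byte_order,
    group_delay = max(0, a1$GRPDLY %||% 0), n_planes = np)
  list(td = new_timedomain(fid, meta), meta = meta)
}

#' Write a Bruker fixture directory from time-domain data
#'
#' Emits `ser`, `acqus` and `acqu2s` files that [read_bruker()] decodes back
#' to the identical matrix. int32 data are written with TopSpin's 1-KiB
#' record padding; values must already be integral for an exact round trip.
#'
#' @param td an `nmr_fid`
#' @param meta an `nmr_acq` (defaults to `td$meta`)
#' @param dir_path output directory; refuses a non-empty existing directory
#'   unless `force = TRUE`
#' @param force overwrite an existing non-empty directory
#' @return `dir_path`, invisibly
#' @export
write_bruker_fixture <- function(td, meta = td$meta, dir_path, force = FALSE) {
  if (dir.exists(dir_path) && length(dir(dir_path)) > 0L && !force)
    nmr_stop("directory ", dir_path, " exists and is not empty (use force = TRUE)")
  dir.create(dir_path, showWarnings = FALSE, recursive = TRUE)
  d <- dim(td$fid)
  td2 <- 2L * d[3]; td1 <- d[2]
  endian <- meta$byte_order
  rec <- bruker_record_bytes(td2, meta$data_type,
                             padded = meta$data_type == "int32")
  per_rec <- rec %/% (if (meta$data_type == "int32") 4L else 8L)
  con <- file(file.path(dir_path, "ser"), "wb")
  for (p in seq_len(d[1])) for (i in seq_len(td1)) {
    z <- td$fid[p, i, ]
    vals <- numeric(per_rec)
    vals[seq_len(td2)] <- as.vector(rbind(Re(z), Im(z)))
    if (meta$data_type == "int32")
      writeBin(as.integer(round(vals)), con, size = 4L, endian = endian)
    else writeBin(vals, con, size = 8L, endian = endian)
  }
  close(con)
  write_jcamp(list(TD = td2, SW_h = meta$sw_hz[1], SFO1 = meta$obs_mhz[1],
                   O1 = meta$carrier_ppm[1] * meta$obs_mhz[1],
                   BYTORDA = if (endian == "little") 0L else 1L,
                   DTYPA = if (meta$data_type == "int32") 0L else 2L,
                   GRPDLY = meta$group_delay, PARMODE = 1L),
              file.path(dir_path, "acqus"), "acqus fixture")
  write_jcamp(list(TD = td1, SW_h = meta$sw_hz[2], SFO1 = meta$obs_mhz[2],
                   O1 = meta$carrier_ppm[2] * meta$obs_mhz[2],
                   FnMODE = mode_to_fnmode(meta$acquisition_mode)),
              file.path(dir_path, "acqu2s"), "acqu2s fixture")
  invisible(dir_path)
}
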