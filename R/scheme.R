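#' Apodization window specification
#'
#' Window kinds mirror the common processing-script tokens: `sine_bell`
#' (SP; shifted sine-bell to the power `pow`), `exponential` (EM; line
#' broadening `lb_hz`), `gaussian` (GM; Gaussian broadening `lb_hz` of that
#' FWHM in Hz) and `none`.
#'
#' @param kind one of `"none"`, `"sine_bell"`, `"exponential"`, `"gaussian"`
#' @param off,end sine-bell start/end as fractions of pi (defaults 0.5 and
#'   0.95 mimic a cosine-squared bell)
#' @param pow sine-bell exponent (> 0)
#' @param lb_hz line broadening in Hz (>= 0)
#' @param gb Gaussian sharpening parameter (reserved; unused by default)
#' @return a `nmr_window` list
#' @export
new_window <- function(kind = c("none", "sine_bell", "exponential", "gaussian"),
                       off = 0.5, end = 0.95, pow = 2, lb_hz = 0, gb = 0) {
  kind <- match.arg(kind)
  if (kind == "sine_bell") {
    if (off < 0 || off > 1 || end < 0 || end > 1 || off > end)
      nmr_stop("sine_bell requires 0 <= off <= end <= 1")
    if (pow <= 0) nmr_stop("sine_bell requires pow > 0")
  }
  if (lb_hz < 0) nmr_stop("lb_hz must be >= 0")
  structure(list(kind = kind, off = off, end = end, pow = pow,
                 lb_hz = lb_hz, gb = gb), class = "nmr_window")
}

#' Phase correction parameters
#'
#' `p1_deg` is the total first-order sweep across the full spectrum with the
#' pivot at point 0 (the downfield edge).
#'
#' @param p0_deg zeroth-order phase in degrees
#' @param p1_deg total first-order phase sweep in degrees
#' @return a `nmr_phase` list
#' @export
new_phase <- function(p0_deg = 0, p1_deg = 0) {
  stopifnot_scalar(p0_deg, "p0_deg"); stopifnot_scalar(p1_deg, "p1_deg")
  structure(list(p0_deg = p0_deg, p1_deg = p1_deg), class = "nmr_phase")
}

dim_scheme <- function(window, zero_fill_folds, solvent_filter, phase,
                       extract_ppm) {
  if (!inherits(window, "nmr_window")) nmr_stop("window must be nmr_window")
  if (zero_fill_folds < 0) nmr_stop("zero_fill_folds must be >= 0")
  if (!identical(phase, "auto") && !inherits(phase, "nmr_phase"))
    nmr_stop("phase must be \"auto\" or an nmr_phase")
  list(window = window, zero_fill_folds = as.integer(zero_fill_folds),
       solvent_filter = isTRUE(solvent_filter), phase = phase,
       extract_ppm = extract_ppm)
}

#' Processing scheme for a 2D / pseudo-3D dataset
#'
#' Bundles the per-dimension window, zero-filling, solvent filter (direct
#' dimension only), extraction window and phase parameters, plus the
#' process-first-plane-only switch. Defaults: sine-bell off = 0.5,
#' end = 0.95, pow = 2 on both dimensions, one fold of zero-filling,
#' automatic phasing along the direct dimension and explicit zero phases
#' along the indirect dimension.
#'
#' @param direct_window,indirect_window `nmr_window` specifications
#' @param direct_zf,indirect_zf zero-fill folds (doublings, >= 0)
#' @param solvent_filter apply the solvent (zero-frequency) filter on direct FIDs
#' @param direct_phase,indirect_phase `"auto"` or an [new_phase()] object
#' @param direct_extract,indirect_extract optional `c(lo, hi)` ppm windows
#' @param first_plane_only process only the first plane of a pseudo-3D set
#' @return an `nmr_scheme` list
#' @export
new_scheme <- function(direct_window = new_window("sine_bell"),
                       indirect_window = new_window("sine_bell"),
                       direct_zf = 1L, indirect_zf = 1L,
                       solvent_filter = FALSE,
                       direct_phase = "auto",
                       indirect_phase = new_phase(0, 0),
                       direct_extract = NULL, indirect_extract = NULL,
                       first_plane_only = FALSE) {
  structure(list(
    direct = dim_scheme(direct_window, direct_zf, solvent_filter,
                        direct_phase, direct_extract),
    indirect = dim_scheme(indirect_window, indirect_zf, FALSE,
                          indirect_phase, indirect_extract),
    first_plane_only = isTRUE(first_plane_only)), class = "nmr_scheme")
}

window_tokens <- function(w) {
  switch(w$kind,
         none = "none",
         sine_bell = sprintf("SP off %g end %g pow %g", w$off, w$end, w$pow),
         exponential = sprintf("EM lb %g", w$lb_hz),
         gaussian = sprintf("GM lb %g gb %g", w$lb_hz, w$gb))
}

parse_window_tokens <- function(s) {
  tok <- strsplit(trimws(s), "\\s+")[[1]]
  kv <- function(name, default) {
    i <- match(name, tok)
    if (is.na(i)) default else as.numeric(tok[i + 1L])
  }
  switch(tok[1],
         none = new_window("none"),
         SP = new_window("sine_bell", off = kv("off", 0.5),
                         end = kv("end", 0.95), pow = kv("pow", 2)),
         EM = new_window("exponential", lb_hz = kv("lb", 0)),
         GM = new_window("gaussian", lb_hz = kv("lb", 0), gb = kv("gb", 0)),
         nmr_stop("unknown window token: ", tok[1]))
}

#' Serialize a processing scheme to a key = value config file
#'
#' Grammar: one `key = value` per line; keys `direct.window`,
#' `direct.zf`, `direct.sol`, `direct.phase`, `direct.ext` and the
#' `indirect.*` counterparts plus `first_plane_only`. Window values use
#' processing-script tokens (`SP off .5 end .95 pow 2`, `EM lb 5`, `none`);
#' phases are `auto` or `p0 p1` in degrees. Unknown keys are a hard error.
#'
#' @param scheme an `nmr_scheme`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_scheme_config <- function(scheme, path) {
  fmt_phase <- function(p) if (identical(p, "auto")) "auto"
    else sprintf("%g %g", p$p0_deg, p$p1_deg)
  lines <- character()
  for (d in c("direct", "indirect")) {
    s <- scheme[[d]]
    lines <- c(lines,
               sprintf("%s.window = %s", d, window_tokens(s$window)),
               sprintf("%s.zf = %d", d, s$zero_fill_folds),
               if (d == "direct") sprintf("direct.sol = %d",
                                          as.integer(s$solvent_filter)),
               sprintf("%s.phase = %s", d, fmt_phase(s$phase)),
               if (!is.null(s$extract_ppm))
                 sprintf("%s.ext = %g %g", d, s$extract_ppm[1], s$extract_ppm[2]))
  }
  lines <- c(lines, sprintf("first_plane_only = %d",
                            as.integer(scheme$first_plane_only)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a processing scheme config written by [write_scheme_config()]
#' @param path config file path
#' @return an `nmr_scheme`
#' @export
read_scheme_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  sch <- new_scheme()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) nmr_stop("bad config line: ", ln)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    if (key == "first_plane_only") {
      sch$first_plane_only <- as.integer(val) != 0L
    } else if (length(parts) == 2L && parts[1] %in% c("direct", "indirect")) {
      d <- parts[1]
      nums <- suppressWarnings(as.numeric(strsplit(val, "\\s+")[[1]]))
      sch[[d]] <- switch(parts[2],
        window = { sch[[d]]$window <- parse_window_tokens(val); sch[[d]] },
        zf = { sch[[d]]$zero_fill_folds <- as.integer(val); sch[[d]] },
        sol = { sch[[d]]$solvent_filter <- as.integer(val) != 0L; sch[[d]] },
        phase = { sch[[d]]$phase <- if (val == "auto") "auto"
                    else new_phase(nums[1], nums[2]); sch[[d]] },
        ext = { sch[[d]]$extract_ppm <- sort(nums[1:2]); sch[[d]] },
        nmr_stop("unknown config key: ", key))
    } else nmr_stop("unknown config key: ", key)
  }
  sch
}
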