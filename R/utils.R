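#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @importFrom stats fft median mad optim nlminb approx integrate lm.fit sd
#' @importFrom utils head tail modifyList
NULL

nmr_log <- function(..., verbose = getOption("nmrdesk.verbose", TRUE)) {
  if (isTRUE(verbose)) message("[nmrdesk] ", ...)
}

nmr_stop <- function(...) stop(..., call. = FALSE)

# swap halves of a vector so zero frequency sits at the centre
fftshift <- function(x) {
  n <- length(x)
  if (n < 2L) return(x)
  h <- n %/% 2L
  c(x[(h + 1L):n], x[1L:h])
}

# reorder FFT bins so index 0 carries +sw/2 (downfield edge) and
# frequency decreases with index: out[k] = X[(N/2 - k) mod N]
fft_to_downfield <- function(x) {
  n <- length(x)
  idx <- ((n %/% 2L) - seq_len(n) + 1L) %% n
  x[idx + 1L]
}

# inverse of fft_to_downfield
downfield_to_fft <- function(y) {
  n <- length(y)
  idx <- ((n %/% 2L) - seq_len(n) + 1L) %% n
  out <- y
  out[idx + 1L] <- y
  out
}

# offset frequency (Hz from carrier) carried by downfield-ordered index k
downfield_offsets_hz <- function(n, sw_hz) {
  sw_hz / 2 - (seq_len(n) - 1L) * sw_hz / n
}

stopifnot_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    nmr_stop(sprintf("'%s' must be a finite numeric scalar", name))
  invisible(x)
}

# round a double to float32 precision (what binary headers can store)
as_float32 <- function(x) {
  con <- rawConnection(raw(0), "r+")
  on.exit(close(con))
  writeBin(as.numeric(x), con, size = 4L)
  seek(con, 0L)
  readBin(con, "numeric", n = length(x), size = 4L)
}
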