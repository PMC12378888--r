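#' Frequency-domain spectrum container
#'
#' Holds the real part of a processed spectrum as a 3D array
#' `[plane, indirect, direct]` (single 2D spectra have one plane), optional
#' hypercomplex imaginary quadrants of identical shape, and the two axis
#' calibrations. Point index 0 along each axis is the downfield edge.
#'
#' @param data matrix `[indirect, direct]` or 3D array `[plane, indirect, direct]`
#' @param axis_direct,axis_indirect `nmr_axis` calibrations
#' @param imag_direct,imag_indirect,imag_both optional imaginary quadrants,
#'   same shape as `data` (direct-dimension imaginary, indirect-dimension
#'   imaginary, and doubly imaginary part)
#' @param noise_sigma optional noise standard deviation
#' @return an object of class `nmr_spectrum`
#' @export
new_spectrum <- function(data, axis_direct, axis_indirect,
                         imag_direct = NULL, imag_indirect = NULL,
                         imag_both = NULL, noise_sigma = NULL) {
  if (is.matrix(data)) data <- array(data, c(1L, nrow(data), ncol(data)))
  if (length(dim(data)) != 3L) nmr_stop("data must be a matrix or 3D array")
  shp <- dim(data)
  for (nm in c("imag_direct", "imag_indirect", "imag_both")) {
    m <- get(nm)
    if (!is.null(m)) {
      if (is.matrix(m)) m <- array(m, c(1L, nrow(m), ncol(m)))
      if (!identical(dim(m), shp)) nmr_stop(nm, " shape differs from data")
      assign(nm, m)
    }
  }
  if (!inherits(axis_direct, "nmr_axis") || !inherits(axis_indirect, "nmr_axis"))
    nmr_stop("axis_direct/axis_indirect must be nmr_axis objects")
  if (axis_direct$n_points != shp[3] || axis_indirect$n_points != shp[2])
    nmr_stop("axis point counts do not match matrix dimensions")
  structure(list(data = data, imag_direct = imag_direct,
                 imag_indirect = imag_indirect, imag_both = imag_both,
                 axis_direct = axis_direct, axis_indirect = axis_indirect,
                 noise_sigma = noise_sigma),
            class = "nmr_spectrum")
}

#' @export
print.nmr_spectrum <- function(x, ...) {
  d <- dim(x$data)
  quad <- c("ri"[!is.null(x$imag_direct)], "ir"[!is.null(x$imag_indirect)],
            "ii"[!is.null(x$imag_both)])
  cat(sprintf("<nmr_spectrum> %d plane(s), %d x %d (indirect x direct)%s\n",
              d[1], d[2], d[3],
              if (length(quad)) paste0(", imag: ", paste(quad, collapse = "+"))
              else ""))
  print(x$axis_direct); print(x$axis_indirect)
  invisible(x)
}

#' Number of planes of a spectrum
#' @param spectrum an `nmr_spectrum`
#' @export
n_planes <- function(spectrum) dim(spectrum$data)[1]

# matrix of one plane (indirect x direct)
plane_matrix <- function(spectrum, plane = 1L, part = "data") {
  m <- spectrum[[part]]
  if (is.null(m)) return(NULL)
  m[plane, , , drop = TRUE]
}

#' Does a spectrum carry direct-dimension imaginary data?
#' @param spectrum an `nmr_spectrum`
#' @export
has_imaginary <- function(spectrum) !is.null(spectrum$imag_direct)
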