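#' Faddeeva function w(z) = exp(-z^2) erfc(-iz)
#'
#' Evaluated for `Im(z) >= 0` by Weideman's rational expansion (N = 64 poles),
#' which is accurate to better than 1e-13 over the upper half plane. This is
#' the scaled complex error function underlying the Voigt profile.
#'
#' @param z complex vector with non-negative imaginary parts
#' @return complex vector of the same length
#' @export
faddeeva_w <- function(z) {
  if (any(Im(z) < -1e-12)) nmr_stop("faddeeva_w requires Im(z) >= 0")
  a <- faddeeva_coefs()
  L <- attr(a, "L")
  Z <- (L + 1i * z) / (L - 1i * z)
  # Horner evaluation of the polynomial in Z with coefficients a (highest first)
  p <- complex(length.out = length(z), real = 0)
  for (ak in a) p <- p * Z + ak
  2 * p / (L - 1i * z)^2 + (1 / sqrt(pi)) / (L - 1i * z)
}

# Weideman (1994) expansion coefficients, computed once and cached
faddeeva_coefs <- local({
  cache <- NULL
  function(N = 64L) {
    if (!is.null(cache)) return(cache)
    M <- 2L * N; M2 <- 2L * M
    k <- seq(-M + 1L, M - 1L)
    L <- sqrt(N / sqrt(2))
    theta <- k * pi / M
    t <- L * tan(theta / 2)
    f <- c(0, exp(-t^2) * (L^2 + t^2))
    a <- Re(fft(fftshift(f))) / M2
    a <- rev(a[2:(N + 1L)])        # highest power first
    attr(a, "L") <- L
    cache <<- a
    a
  }
})

#' Voigt profile value
#'
#' Area-normalised Voigt lineshape: the convolution of a Gaussian of standard
#' deviation `sigma` with a Lorentzian of half-width-at-half-maximum `gamma`,
#' evaluated at offset `dx` from the centre. Degenerate widths fall back to
#' the pure Gaussian / Lorentzian closed forms.
#'
#' @param dx offset(s) from the peak centre (points)
#' @param sigma Gaussian standard deviation (points, >= 0)
#' @param gamma Lorentzian HWHM (points, >= 0); `sigma + gamma` must be > 0
#' @return numeric vector `V(dx)` with unit area
#' @export
voigt_value <- function(dx, sigma, gamma) {
  if (sigma < 0 || gamma < 0) nmr_stop("sigma and gamma must be >= 0")
  if (sigma + gamma <= 0) nmr_stop("sigma + gamma must be > 0")
  if (sigma < 1e-13 * max(1, gamma)) {           # Lorentzian limit
    return(gamma / (pi * (dx^2 + gamma^2)))
  }
  if (gamma < 1e-13 * max(1, sigma)) {           # Gaussian limit
    return(exp(-dx^2 / (2 * sigma^2)) / (sigma * sqrt(2 * pi)))
  }
  z <- complex(real = dx, imaginary = gamma) / (sigma * sqrt(2))
  Re(faddeeva_w(z)) / (sigma * sqrt(2 * pi))
}

# unit-height Voigt shape: V(dx)/V(0)
voigt_shape <- function(dx, sigma, gamma) {
  voigt_value(dx, sigma, gamma) / voigt_value(0, sigma, gamma)
}
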