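# Downstream analysis of pseudo-3D fits: mono-exponential relaxation rates
# and CEST profiles from per-plane peak heights.

#' Fit a mono-exponential decay to a relaxation series
#'
#' Least squares of `h(t) = A * exp(-R * t)`, initialized from the
#' log-linear regression of the positive heights; the standard error of `R`
#' comes from the Jacobian at the optimum. Heights may be on any (e.g.
#' relative Z_A) scale: the rate is scale-invariant.
#'
#' @param delays_s relaxation delays in seconds, strictly increasing, >= 3
#' @param heights peak heights at those delays
#' @return a list (class `nmr_rate_fit`) with `rate_per_s`, `amplitude`,
#'   `rate_stderr`, `r_squared`
#' @export
fit_exponential <- function(delays_s, heights) {
  t <- as.numeric(delays_s); h <- as.numeric(heights)
  if (length(t) < 3L || length(t) != length(h))
    nmr_stop("need >= 3 (delay, height) pairs of equal length")
  if (any(diff(t) <= 0)) nmr_stop("delays must be strictly increasing")
  if (sum(h <= 0) > length(h) / 2)
    nmr_stop("decay model inapplicable: most heights are non-positive")
  pos <- h > 0
  lf <- stats::lm.fit(cbind(1, t[pos]), log(h[pos]))
  A0 <- exp(unname(lf$coefficients[1])); R0 <- -unname(lf$coefficients[2])
  obj <- function(p) sum((h - p[1] * exp(-p[2] * t))^2)
  opt <- optim(c(A0, R0), obj, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
  A <- opt$par[1]; R <- opt$par[2]
  J <- cbind(exp(-R * t), -A * t * exp(-R * t))
  r <- h - A * exp(-R * t)
  dof <- max(1L, length(t) - 2L)
  s2 <- sum(r^2) / dof
  cov <- tryCatch(s2 * solve(crossprod(J)), error = function(e) matrix(NA, 2, 2))
  ss_tot <- sum((h - mean(h))^2)
  structure(list(rate_per_s = R, amplitude = A,
                 rate_stderr = sqrt(max(0, cov[2, 2])),
                 r_squared = if (ss_tot > 0) 1 - sum(r^2) / ss_tot else NA_real_),
            class = "nmr_rate_fit")
}

#' CEST profile from per-plane heights
#'
#' Normalizes every plane intensity by the reference (off-resonance
#' saturation) plane and orders the profile by saturation offset.
#'
#' @param heights per-plane peak heights
#' @param offsets_hz saturation offsets (one per plane)
#' @param reference_index 1-based index of the reference plane
#' @return data frame with columns `offset_hz`, `intensity` (normalized)
#' @export
cest_profile <- function(heights, offsets_hz, reference_index = 1L) {
  if (length(heights) != length(offsets_hz))
    nmr_stop("heights and offsets must have equal length")
  ref <- heights[reference_index]
  if (!is.finite(ref) || ref <= 0)
    nmr_stop("reference intensity must be > 0")
  ord <- order(offsets_hz)
  data.frame(offset_hz = offsets_hz[ord], intensity = heights[ord] / ref)
}

#' Relaxation rates for every peak of a fitted pseudo-3D peak list
#'
#' @param fitted_peaks an `nmr_peaks` carrying `Z_A0`, `Z_A1`, ... columns
#' @param delays_s relaxation delays, one per plane
#' @return data frame (one row per peak) with `label`, `rate_per_s`,
#'   `amplitude`, `rate_stderr`, `r_squared`; serializable as TSV
#' @export
rates_from_peaklist <- function(fitted_peaks, delays_s) {
  za <- za_columns(fitted_peaks)
  if (length(za) == 0L) nmr_stop("peak list has no Z_A plane-height columns")
  if (length(za) != length(delays_s))
    nmr_stop("delays length ", length(delays_s), " != Z_A column count ",
             length(za), " (peak ", fitted_peaks$label[1] %||% "?", ")")
  out <- lapply(seq_len(nrow(fitted_peaks)), function(i) {
    hs <- as.numeric(fitted_peaks[i, za])
    f <- tryCatch(fit_exponential(delays_s, hs), error = function(e)
      nmr_stop("peak ", fitted_peaks$label[i], ": ", conditionMessage(e)))
    data.frame(label = fitted_peaks$label[i], rate_per_s = f$rate_per_s,
               amplitude = f$amplitude, rate_stderr = f$rate_stderr,
               r_squared = f$r_squared)
  })
  do.call(rbind, out)
}
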