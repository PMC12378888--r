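# Peak picking and lineshape deconvolution: robust noise estimation,
# 8-neighbour maxima picking with parabolic refinement, region clustering,
# and (pseudo-3D) Voigt/Gaussian/Lorentzian least-squares fitting with
# heights solved by linear projection inside a bounded nonlinear search.

#' Fitting options for deconvolution
#'
#' @param lineshape `"voigt"`, `"gaussian"` or `"lorentzian"` (separable 1D
#'   product along the two axes)
#' @param max_iterations optimizer iteration cap per region
#' @param cluster_threshold_sigma region mask threshold in noise sigmas
#' @param region_pad_points padding added around each region bounding box
#' @param min_separation_points minimum separation retained between picked
#'   peaks (closer duplicates are merged)
#' @return an `nmr_fit_options` list
#' @export
new_fit_options <- function(lineshape = c("voigt", "gaussian", "lorentzian"),
                            max_iterations = 100L,
                            cluster_threshold_sigma = 5.5,
                            region_pad_points = 3L,
                            min_separation_points = 2L) {
  lineshape <- match.arg(lineshape)
  if (cluster_threshold_sigma <= 0)
    nmr_stop("cluster_threshold_sigma must be > 0")
  structure(list(lineshape = lineshape,
                 max_iterations = as.integer(max_iterations),
                 cluster_threshold_sigma = cluster_threshold_sigma,
                 region_pad_points = as.integer(region_pad_points),
                 min_separation_points = as.integer(min_separation_points)),
            class = "nmr_fit_options")
}

#' Robust noise estimate of a spectrum
#'
#' 1.4826 x the median absolute deviation, computed over 32 x 32 sub-blocks
#' of the real matrix; the median of the block estimates resists signal
#' contamination.
#'
#' @param spectrum an `nmr_spectrum` or a numeric matrix
#' @param block block edge length in points
#' @return estimated noise standard deviation
#' @export
estimate_noise <- function(spectrum, block = 32L) {
  m <- if (inherits(spectrum, "nmr_spectrum")) plane_matrix(spectrum, 1L)
       else as.matrix(spectrum)
  if (length(m) == 0L) nmr_stop("empty matrix")
  nr <- nrow(m); nc <- ncol(m)
  bi <- unique(pmin(seq(1L, nr, by = block), nr))
  bj <- unique(pmin(seq(1L, nc, by = block), nc))
  ests <- c()
  for (i0 in bi) for (j0 in bj) {
    blk <- m[i0:min(nr, i0 + block - 1L), j0:min(nc, j0 + block - 1L)]
    ests <- c(ests, stats::mad(as.numeric(blk)))
  }
  stats::median(ests)
}

#' Pick peaks as interpolated local maxima
#'
#' Returns every point of the real matrix strictly greater than all eight
#' neighbours and above `threshold_sigma` times the noise, refined to
#' sub-point positions by 1D parabolic interpolation along each axis. Peaks
#' are ordered by (row, col) index.
#'
#' @param spectrum an `nmr_spectrum` (plane 1 is picked)
#' @param threshold_sigma detection threshold in noise sigmas
#' @param noise_sigma noise level; estimated if missing
#' @return an `nmr_peaks` with positions in ppm (and point-coordinate
#'   columns `x_pt`, `y_pt`)
#' @export
pick_peaks <- function(spectrum, threshold_sigma = 5.5, noise_sigma = NULL) {
  m <- plane_matrix(spectrum, 1L)
  noise <- noise_sigma %||% spectrum$noise_sigma %||% estimate_noise(m)
  thr <- threshold_sigma * noise
  nr <- nrow(m); nc <- ncol(m)
  if (nr < 3L || nc < 3L) return(annotate_points(new_peaklist(), spectrum))
  C <- m[2:(nr - 1L), 2:(nc - 1L)]
  is_max <- C > thr &
    C > m[1:(nr - 2L), 2:(nc - 1L)] & C > m[3:nr, 2:(nc - 1L)] &
    C > m[2:(nr - 1L), 1:(nc - 2L)] & C > m[2:(nr - 1L), 3:nc] &
    C > m[1:(nr - 2L), 1:(nc - 2L)] & C > m[1:(nr - 2L), 3:nc] &
    C > m[3:nr, 1:(nc - 2L)] & C > m[3:nr, 3:nc]
  hits <- which(is_max, arr.ind = TRUE)
  if (nrow(hits) == 0L) return(annotate_points(new_peaklist(), spectrum))
  hits <- hits[order(hits[, 1L], hits[, 2L]), , drop = FALSE]
  ii <- hits[, 1L] + 1L; jj <- hits[, 2L] + 1L
  para <- function(fm, f0, fp) {
    den <- fm - 2 * f0 + fp
    ifelse(abs(den) > 0, pmax(-0.5, pmin(0.5, 0.5 * (fm - fp) / den)), 0)
  }
  di <- para(m[cbind(ii - 1L, jj)], m[cbind(ii, jj)], m[cbind(ii + 1L, jj)])
  dj <- para(m[cbind(ii, jj - 1L)], m[cbind(ii, jj)], m[cbind(ii, jj + 1L)])
  y_pt <- (ii - 1L) + di; x_pt <- (jj - 1L) + dj
  pk <- new_peaklist(x_ppm = pt_to_ppm(spectrum$axis_direct, x_pt),
                     y_ppm = pt_to_ppm(spectrum$axis_indirect, y_pt),
                     height = m[cbind(ii, jj)])
  pk$x_pt <- x_pt; pk$y_pt <- y_pt
  pk
}

annotate_points <- function(pk, spectrum) {
  pk$x_pt <- if (nrow(pk)) ppm_to_pt(spectrum$axis_direct, pk$x_ppm) else numeric()
  pk$y_pt <- if (nrow(pk)) ppm_to_pt(spectrum$axis_indirect, pk$y_ppm) else numeric()
  pk
}

# nonlinear parameters per peak for a given lineshape
shape_par_count <- function(lineshape) {
  if (lineshape == "voigt") 6L else 4L
}

# unit-height separable lineshape of one peak over a patch grid
peak_basis <- function(theta, lineshape, ny, nx) {
  x <- theta[1]; y <- theta[2]
  if (lineshape == "voigt") {
    sx <- theta[3]; gx <- theta[4]; sy <- theta[5]; gy <- theta[6]
  } else if (lineshape == "gaussian") {
    sx <- theta[3]; gx <- 0; sy <- theta[4]; gy <- 0
  } else {
    sx <- 0; gx <- theta[3]; sy <- 0; gy <- theta[4]
  }
  vx <- voigt_shape((seq_len(nx) - 1) - x, sx, gx)
  vy <- voigt_shape((seq_len(ny) - 1) - y, sy, gy)
  outer(vy, vx)
}

# pack/unpack nonlinear parameters, with bounds
region_theta <- function(peaks_pt, lineshape, ny, nx, wmin = 0.3) {
  k <- nrow(peaks_pt)
  npar <- shape_par_count(lineshape)
  theta <- numeric(k * npar); lo <- theta; hi <- theta
  wmax <- max(ny, nx)
  for (j in seq_len(k)) {
    off <- (j - 1L) * npar
    fw <- max(wmin * 2, peaks_pt$fwhm_x[j] %||% 3)
    fh <- max(wmin * 2, peaks_pt$fwhm_y[j] %||% 3)
    pos <- c(peaks_pt$x[j], peaks_pt$y[j])
    if (lineshape == "voigt") {
      init <- c(pos, fw / 4, fw / 4, fh / 4, fh / 4)
      lw <- c(0, 0, rep(wmin / 2, 4)); up <- c(nx - 1, ny - 1, rep(wmax, 4))
    } else if (lineshape == "gaussian") {
      init <- c(pos, fw / 2.355, fh / 2.355)
      lw <- c(0, 0, wmin, wmin); up <- c(nx - 1, ny - 1, wmax, wmax)
    } else {
      init <- c(pos, fw / 2, fh / 2)
      lw <- c(0, 0, wmin, wmin); up <- c(nx - 1, ny - 1, wmax, wmax)
    }
    theta[off + seq_len(npar)] <- pmin(pmax(init, lw), up)
    lo[off + seq_len(npar)] <- lw
    hi[off + seq_len(npar)] <- up
  }
  list(theta = theta, lower = lo, upper = hi, npar = npar)
}

# heights by linear least squares given the basis; patches is a list of
# plane matrices; returns list(heights = [k x planes], rss)
solve_heights <- function(B, patches) {
  qrB <- qr(B)
  H <- matrix(0, ncol(B), length(patches))
  rss <- 0
  for (p in seq_along(patches)) {
    yv <- as.numeric(patches[[p]])
    h <- qr.coef(qrB, yv)
    h[is.na(h)] <- 0
    r <- yv - B %*% h
    H[, p] <- h
    rss <- rss + sum(r^2)
  }
  list(heights = H, rss = rss)
}

region_rss <- function(theta, lineshape, ny, nx, patches) {
  k <- length(theta) / shape_par_count(lineshape)
  npar <- shape_par_count(lineshape)
  B <- matrix(0, ny * nx, k)
  for (j in seq_len(k))
    B[, j] <- as.numeric(peak_basis(theta[(j - 1L) * npar + seq_len(npar)],
                                    lineshape, ny, nx))
  solve_heights(B, patches)$rss
}

#' Fit all peaks of one region patch
#'
#' Least squares of a sum of separable Voigt/Gaussian/Lorentzian products
#' over the patch (all planes jointly, sharing positions and widths, with
#' per-plane heights solved linearly at every step). Positions are bounded
#' to the patch and widths to `[0.3, patch size]` points. Peaks whose
#' fitted height stays below 3 x noise are culled and the region refit once.
#'
#' @param patch numeric matrix or list of plane matrices (same shape)
#' @param initial_peaks data frame with 0-based patch coordinates `x`, `y`
#'   and optional `fwhm_x`, `fwhm_y` starting widths
#' @param options an [new_fit_options()]
#' @param noise noise sigma used by the culling rule
#' @return list with `peaks` (patch coordinates, widths, `height`, matrix
#'   `plane_heights`), `converged`, `rss`
#' @export
fit_region <- function(patch, initial_peaks, options = new_fit_options(),
                       noise = 0) {
  patches <- if (is.list(patch)) patch else list(patch)
  ny <- nrow(patches[[1]]); nx <- ncol(patches[[1]])
  if (nrow(initial_peaks) == 0L) nmr_stop("fit_region needs >= 1 initial peak")
  run <- function(pks) {
    setup <- region_theta(pks, options$lineshape, ny, nx)
    npar <- setup$npar
    ctrl <- list(iter.max = options$max_iterations,
                 eval.max = 40L * options$max_iterations,
                 rel.tol = 1e-14, x.tol = 1e-12)
    fn <- function(th) region_rss(th, options$lineshape, ny, nx, patches)
    gr <- function(th) {           # central differences: stable deep descent
      vapply(seq_along(th), function(i) {
        h <- 1e-6 * max(1, abs(th[i]))
        tp <- th; tp[i] <- th[i] + h
        tm <- th; tm[i] <- th[i] - h
        (fn(tp) - fn(tm)) / (2 * h)
      }, 0)
    }
    opt <- nlminb(setup$theta, fn, gradient = gr, lower = setup$lower,
                  upper = setup$upper, control = ctrl)
    k <- nrow(pks)
    B <- matrix(0, ny * nx, k)
    for (j in seq_len(k))
      B[, j] <- as.numeric(peak_basis(
        opt$par[(j - 1L) * npar + seq_len(npar)], options$lineshape, ny, nx))
    hs <- solve_heights(B, patches)
    list(opt = opt, theta = opt$par, heights = hs$heights, rss = hs$rss,
         npar = npar)
  }
  res <- run(initial_peaks)
  hmax <- apply(abs(res$heights), 1L, max)
  keep <- hmax >= 3 * noise
  if (!all(keep)) {
    if (!any(keep))
      return(list(peaks = NULL, converged = TRUE, rss = sum(
        vapply(patches, function(m) sum(m^2), 0))))
    npar <- res$npar
    kept <- initial_peaks[keep, , drop = FALSE]
    for (j in seq_len(sum(keep))) {
      src <- which(keep)[j]
      kept$x[j] <- res$theta[(src - 1L) * npar + 1L]
      kept$y[j] <- res$theta[(src - 1L) * npar + 2L]
    }
    res <- run(kept)
    initial_peaks <- kept
  }
  npar <- res$npar
  k <- nrow(initial_peaks)
  get <- function(i) vapply(seq_len(k), function(j)
    res$theta[(j - 1L) * npar + i], 0)
  if (options$lineshape == "voigt") {
    sx <- get(3); gx <- get(4); sy <- get(5); gy <- get(6)
  } else if (options$lineshape == "gaussian") {
    sx <- get(3); sy <- get(4); gx <- rep(0, k); gy <- rep(0, k)
  } else {
    gx <- get(3); gy <- get(4); sx <- rep(0, k); sy <- rep(0, k)
  }
  list(peaks = data.frame(x = get(1), y = get(2), sigma_x = sx, gamma_x = gx,
                          sigma_y = sy, gamma_y = gy,
                          height = res$heights[, 1L]),
       plane_heights = res$heights,
       converged = res$opt$convergence == 0 ||
         grepl("relative convergence|X-convergence|both X|singular convergence",
               res$opt$message %||% ""),
       rss = res$rss)
}

# 8-connected components of a logical matrix; returns integer label matrix
connected_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  idx <- which(mask)
  for (s in idx) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    lab[s] <- cur
    while (length(queue)) {
      v <- queue[[length(queue)]]
      queue <- queue[-length(queue)]
      i <- (v - 1L) %% nr + 1L; j <- (v - 1L) %/% nr + 1L
      for (di in -1:1) for (dj in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii >= 1L && ii <= nr && jj >= 1L && jj <= nc) {
          w <- (jj - 1L) * nr + ii
          if (mask[w] && lab[w] == 0L) { lab[w] <- cur; queue <- c(queue, w) }
        }
      }
    }
  }
  lab
}

# crude FWHM estimate along a row/column around a maximum (points)
est_fwhm <- function(v, i0) {
  h <- v[i0] / 2
  n <- length(v)
  r <- i0; while (r < n && v[r + 1L] > h) r <- r + 1L
  l <- i0; while (l > 1L && v[l - 1L] > h) l <- l - 1L
  max(2, (r - l))
}

#' Deconvolute a spectrum into fitted peaks
#'
#' The above-threshold mask (`cluster_threshold_sigma` x noise,
#' 8-connectivity) is split into connected regions, padded by
#' `region_pad_points`; each region is fit independently with
#' [fit_region()] and the results are merged. The reconstructed spectrum is
#' the sum of all fitted peaks evaluated on the full grid. For multi-plane
#' input all planes are fit jointly with shared positions and lineshapes
#' and per-plane heights (the pseudo-3D model).
#'
#' @param spectrum an `nmr_spectrum`
#' @param peaks initial `nmr_peaks` (e.g. from [pick_peaks()])
#' @param options an [new_fit_options()]
#' @param relative_heights report plane heights relative to plane 0
#' @return list (class `nmr_fit`) with `peaks`, `reconstructed`,
#'   `residual_rms`, `converged` (per region), `noise_sigma`
#' @export
fit_peaks <- function(spectrum, peaks, options = new_fit_options(),
                      relative_heights = TRUE) {
  if (nrow(peaks) == 0L) nmr_stop("fit_peaks needs a non-empty peak list")
  np <- n_planes(spectrum)
  m1 <- plane_matrix(spectrum, 1L)
  nr <- nrow(m1); nc <- ncol(m1)
  noise <- spectrum$noise_sigma %||% estimate_noise(spectrum)
  pk <- annotate_points(as.data.frame(peaks), spectrum)
  inside <- pk$x_pt >= 0 & pk$x_pt <= nc - 1 & pk$y_pt >= 0 & pk$y_pt <= nr - 1
  if (!all(inside)) {
    warning(sum(!inside), " peak(s) outside the spectrum dropped")
    pk <- pk[inside, , drop = FALSE]
  }
  if (nrow(pk) == 0L) nmr_stop("no peaks inside the spectrum")
  # merge near-duplicate starting positions (keep the taller of each pair)
  if (nrow(pk) > 1L && options$min_separation_points > 0L) {
    ord <- order(-abs(pk$height %||% rep(0, nrow(pk))))
    pk <- pk[ord, , drop = FALSE]
    keep <- rep(TRUE, nrow(pk))
    for (i in seq_len(nrow(pk))[-1L]) {
      d <- sqrt((pk$x_pt[seq_len(i - 1L)] - pk$x_pt[i])^2 +
                (pk$y_pt[seq_len(i - 1L)] - pk$y_pt[i])^2)
      if (any(d[keep[seq_len(i - 1L)]] < options$min_separation_points))
        keep[i] <- FALSE
    }
    pk <- pk[keep, , drop = FALSE]
  }
  mask <- m1 > options$cluster_threshold_sigma * noise
  lab <- connected_components(mask)
  ri <- pmin(pmax(round(pk$y_pt) + 1L, 1L), nr)
  ci <- pmin(pmax(round(pk$x_pt) + 1L, 1L), nc)
  comp <- lab[cbind(ri, ci)]
  # peaks off the mask become singleton pseudo-components
  nxt <- max(lab) + 1L
  for (i in which(comp == 0L)) { comp[i] <- nxt; nxt <- nxt + 1L }
  pad <- options$region_pad_points
  regions <- list()
  for (cid in unique(comp)) {
    sel <- which(comp == cid)
    if (cid <= max(lab) && any(lab == cid)) {
      cells <- which(lab == cid, arr.ind = TRUE)
      r0 <- max(1L, min(cells[, 1L]) - pad); r1 <- min(nr, max(cells[, 1L]) + pad)
      c0 <- max(1L, min(cells[, 2L]) - pad); c1 <- min(nc, max(cells[, 2L]) + pad)
    } else {
      r0 <- max(1L, min(ri[sel]) - 4L * pad); r1 <- min(nr, max(ri[sel]) + 4L * pad)
      c0 <- max(1L, min(ci[sel]) - 4L * pad); c1 <- min(nc, max(ci[sel]) + 4L * pad)
    }
    init <- data.frame(x = pk$x_pt[sel] - (c0 - 1L),
                       y = pk$y_pt[sel] - (r0 - 1L))
    init$fwhm_x <- vapply(sel, function(i) est_fwhm(m1[ri[i], ], ci[i]), 0)
    init$fwhm_y <- vapply(sel, function(i) est_fwhm(m1[, ci[i]], ri[i]), 0)
    regions[[length(regions) + 1L]] <- list(r0 = r0, r1 = r1, c0 = c0,
                                            c1 = c1, init = init)
  }
  # evaluate a fitted region's peaks over a sub-window of the full grid
  eval_region <- function(res, reg, r0, r1, c0, c1) {
    out <- lapply(seq_len(np), function(p) matrix(0, r1 - r0 + 1L, c1 - c0 + 1L))
    if (is.null(res$peaks)) return(out)
    for (j in seq_len(nrow(res$peaks))) {
      bx <- voigt_shape((c0:c1) - 1 - (res$peaks$x[j] + reg$c0 - 1L),
                        res$peaks$sigma_x[j], res$peaks$gamma_x[j])
      by <- voigt_shape((r0:r1) - 1 - (res$peaks$y[j] + reg$r0 - 1L),
                        res$peaks$sigma_y[j], res$peaks$gamma_y[j])
      for (p in seq_len(np))
        out[[p]] <- out[[p]] + res$plane_heights[j, p] * outer(by, bx)
    }
    out
  }
  run_pass <- function(results) {
    lapply(seq_along(regions), function(k) {
      reg <- regions[[k]]
      patches <- lapply(seq_len(np), function(p)
        plane_matrix(spectrum, p)[reg$r0:reg$r1, reg$c0:reg$c1, drop = FALSE])
      if (!is.null(results)) {
        # subtract the other regions' current models (cross-region tails)
        for (k2 in seq_along(regions)) {
          if (k2 == k || is.null(results[[k2]]$peaks)) next
          tails <- eval_region(results[[k2]], regions[[k2]], reg$r0, reg$r1,
                               reg$c0, reg$c1)
          for (p in seq_len(np)) patches[[p]] <- patches[[p]] - tails[[p]]
        }
        prev <- results[[k]]
        if (is.null(prev$peaks)) return(prev)
        init <- data.frame(x = prev$peaks$x, y = prev$peaks$y,
                           fwhm_x = 2.355 * prev$peaks$sigma_x +
                             2 * prev$peaks$gamma_x,
                           fwhm_y = 2.355 * prev$peaks$sigma_y +
                             2 * prev$peaks$gamma_y)
      } else init <- reg$init
      fit_region(patches, init, options, noise)
    })
  }
  results <- run_pass(NULL)
  if (length(regions) > 1L) results <- run_pass(results)
  fitted <- list(); conv <- logical(0); plane_h <- list()
  for (k in seq_along(regions)) {
    res <- results[[k]]
    conv <- c(conv, res$converged)
    if (!is.null(res$peaks)) {
      res$peaks$x <- res$peaks$x + (regions[[k]]$c0 - 1L)
      res$peaks$y <- res$peaks$y + (regions[[k]]$r0 - 1L)
      fitted[[length(fitted) + 1L]] <- res$peaks
      plane_h[[length(plane_h) + 1L]] <- res$plane_heights
    }
  }
  if (length(fitted) == 0L) {
    out_pk <- new_peaklist()
    recon <- array(0, dim(spectrum$data))
  } else {
    allpk <- do.call(rbind, fitted)
    H <- do.call(rbind, plane_h)
    recon <- array(0, dim(spectrum$data))
    for (j in seq_len(nrow(allpk))) {
      bx <- voigt_shape((seq_len(nc) - 1) - allpk$x[j],
                        allpk$sigma_x[j], allpk$gamma_x[j])
      by <- voigt_shape((seq_len(nr) - 1) - allpk$y[j],
                        allpk$sigma_y[j], allpk$gamma_y[j])
      for (p in seq_len(np))
        recon[p, , ] <- recon[p, , ] + H[j, p] * outer(by, bx)
    }
    ph <- H
    if (np > 1L && relative_heights) ph <- H / H[, 1L]
    out_pk <- new_peaklist(
      x_ppm = pt_to_ppm(spectrum$axis_direct, allpk$x),
      y_ppm = pt_to_ppm(spectrum$axis_indirect, allpk$y),
      height = allpk$height,
      sigma_x = allpk$sigma_x, sigma_y = allpk$sigma_y,
      gamma_x = allpk$gamma_x, gamma_y = allpk$gamma_y,
      plane_heights = if (np > 1L) ph)
    out_pk$x_pt <- allpk$x; out_pk$y_pt <- allpk$y
  }
  resid <- spectrum$data - recon
  structure(list(
    peaks = out_pk,
    reconstructed = new_spectrum(recon, spectrum$axis_direct,
                                 spectrum$axis_indirect),
    residual_rms = sqrt(mean(resid^2)),
    converged = conv, noise_sigma = noise), class = "nmr_fit")
}

#' Pseudo-3D constrained fit: shared shapes, per-plane heights
#'
#' Joint least squares over all planes with one position and lineshape per
#' peak and free per-plane heights, reported as `Z_A0`, `Z_A1`, ...
#' (relative to plane 0 by default).
#'
#' @inheritParams fit_peaks
#' @return an `nmr_fit` (see [fit_peaks()])
#' @export
fit_pseudo3d <- function(spectrum, peaks, options = new_fit_options(),
                         relative_heights = TRUE) {
  if (n_planes(spectrum) < 2L)
    nmr_stop("fit_pseudo3d requires >= 2 planes")
  fit_peaks(spectrum, peaks, options, relative_heights)
}

#' Edit a peak list
#'
#' Pure functional add/move/delete; indices are re-assigned sequentially.
#'
#' @param peaks an `nmr_peaks`
#' @param action `"add"`, `"move"` or `"delete"`
#' @param payload for `add`: list/row with at least `x_ppm`, `y_ppm`;
#'   for `move`: list `(index, x_ppm, y_ppm)`; for `delete`: list `(index)`
#' @return the edited `nmr_peaks`
#' @export
edit_peaklist <- function(peaks, action = c("add", "move", "delete"), payload) {
  action <- match.arg(action)
  df <- as.data.frame(peaks)
  if (action == "add") {
    row <- df[0, ]
    new <- as.list(payload)
    row[1L, names(new)[names(new) %in% names(df)]] <-
      new[names(new) %in% names(df)]
    if (!"label" %in% names(new) || is.na(row$label[1]))
      row$label <- sprintf("P%d", nrow(df) + 1L)
    df <- rbind(df, row)
  } else {
    i <- payload$index
    if (is.null(i) || length(i) != 1L || is.na(i) || i < 1L || i > nrow(df))
      nmr_stop("peak index out of range")
    if (action == "delete") df <- df[-i, , drop = FALSE]
    else {
      if (!is.null(payload$x_ppm)) df$x_ppm[i] <- payload$x_ppm
      if (!is.null(payload$y_ppm)) df$y_ppm[i] <- payload$y_ppm
    }
  }
  df$index <- seq_len(nrow(df))
  rownames(df) <- NULL
  class(df) <- c("nmr_peaks", "data.frame")
  df
}
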