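# Contour computation (marching squares) and deterministic static rendering:
# multi-spectrum overlays with independent referencing, peak labels with
# greedy de-overlap, 1D traces, and 3D surface / terrace views.

#' Contour level specification
#'
#' @param mode `"geometric"` (each level `factor` times the previous) or
#'   `"linear"` (constant step)
#' @param lowest lowest contour level
#' @param factor_or_step geometric factor (> 1) or linear step (> 0)
#' @param count maximum number of levels
#' @return an `nmr_levels` list
#' @export
new_levels <- function(mode = c("geometric", "linear"), lowest,
                       factor_or_step, count) {
  mode <- match.arg(mode)
  if (mode == "geometric" && factor_or_step <= 1)
    nmr_stop("geometric levels require factor > 1")
  if (mode == "linear" && factor_or_step <= 0)
    nmr_stop("linear levels require step > 0")
  structure(list(mode = mode, lowest = lowest,
                 factor_or_step = factor_or_step, count = as.integer(count)),
            class = "nmr_levels")
}

level_values <- function(levels, max_val = Inf) {
  v <- if (levels$mode == "geometric")
    levels$lowest * levels$factor_or_step^(seq_len(levels$count) - 1L)
  else levels$lowest + levels$factor_or_step * (seq_len(levels$count) - 1L)
  v[v <= max_val | seq_along(v) == 1L]
}

#' Default contour levels for a spectrum
#'
#' Geometric levels starting at 5.5 x the noise sigma with factor 1.4,
#' at most 20 levels, capped below the matrix maximum.
#'
#' @param spectrum an `nmr_spectrum` or numeric matrix
#' @return an `nmr_levels`
#' @export
default_levels <- function(spectrum) {
  m <- if (inherits(spectrum, "nmr_spectrum")) plane_matrix(spectrum, 1L)
       else as.matrix(spectrum)
  noise <- if (inherits(spectrum, "nmr_spectrum"))
    spectrum$noise_sigma %||% estimate_noise(m) else estimate_noise(m)
  mx <- max(m)
  if (noise <= 0 && mx <= 0) {
    warning("zero noise and zero signal: single level at 1.0")
    return(new_levels("geometric", 1.0, 1.4, 1L))
  }
  lowest <- if (noise > 0) 5.5 * noise else mx / 100
  count <- 20L
  if (mx > lowest)
    count <- max(1L, min(20L, floor(log(mx / lowest) / log(1.4)) + 1L))
  new_levels("geometric", lowest, 1.4, count)
}

# marching-squares segments of one level; returns matrix [n, 4] of
# (x1, y1, x2, y2) in fractional 0-based point units (x = column, y = row)
ms_segments <- function(m, lev) {
  nr <- nrow(m); nc <- ncol(m)
  if (nr < 2L || nc < 2L) return(matrix(0, 0L, 4L))
  a <- m[-nr, -nc]; b <- m[-nr, -1L]; cc <- m[-1L, -1L]; d <- m[-1L, -nc]
  case <- (a >= lev) + 2L * (b >= lev) + 4L * (cc >= lev) + 8L * (d >= lev)
  hit <- which(case > 0L & case < 15L, arr.ind = TRUE)
  if (nrow(hit) == 0L) return(matrix(0, 0L, 4L))
  segs <- vector("list", nrow(hit))
  for (s in seq_len(nrow(hit))) {
    i <- hit[s, 1L]; j <- hit[s, 2L]
    va <- a[i, j]; vb <- b[i, j]; vc <- cc[i, j]; vd <- d[i, j]
    top <- c(j - 1 + (lev - va) / (vb - va), i - 1)
    right <- c(j, i - 1 + (lev - vb) / (vc - vb))
    bottom <- c(j - 1 + (lev - vd) / (vc - vd), i)
    left <- c(j - 1, i - 1 + (lev - va) / (vd - va))
    cs <- case[i, j]
    pair <- switch(cs,
      list(c(left, top)),                      # 1
      list(c(top, right)),                     # 2
      list(c(left, right)),                    # 3
      list(c(right, bottom)),                  # 4
      { ctr <- (va + vb + vc + vd) / 4         # 5: saddle (a, c inside)
        if (ctr >= lev) list(c(top, right), c(left, bottom))
        else list(c(left, top), c(right, bottom)) },
      list(c(top, bottom)),                    # 6
      list(c(left, bottom)),                   # 7
      list(c(bottom, left)),                   # 8
      list(c(top, bottom)),                    # 9
      { ctr <- (va + vb + vc + vd) / 4         # 10: saddle (b, d inside)
        if (ctr >= lev) list(c(left, top), c(right, bottom))
        else list(c(top, right), c(left, bottom)) },
      list(c(right, bottom)),                  # 11
      list(c(left, right)),                    # 12
      list(c(top, right)),                     # 13
      list(c(left, top)))                      # 14
    segs[[s]] <- do.call(rbind, pair)
  }
  do.call(rbind, segs)
}

# chain segments into polylines by matching endpoints
chain_segments <- function(segs) {
  n <- nrow(segs)
  if (n == 0L) return(list())
  key <- function(x, y) sprintf("%.8f,%.8f", x, y)
  ends <- new.env(hash = TRUE, parent = emptyenv())
  addk <- function(k, s) assign(k, c(get0(k, envir = ends, ifnotfound = integer()),
                                     s), envir = ends)
  for (s in seq_len(n)) {
    addk(key(segs[s, 1L], segs[s, 2L]), s)
    addk(key(segs[s, 3L], segs[s, 4L]), s)
  }
  used <- logical(n)
  out <- list()
  for (s0 in seq_len(n)) {
    if (used[s0]) next
    used[s0] <- TRUE
    pts <- rbind(segs[s0, 1:2], segs[s0, 3:4])
    for (dir in 1:2) {
      if (dir == 2L) pts <- pts[rev(seq_len(nrow(pts))), , drop = FALSE]
      repeat {
        tailp <- pts[nrow(pts), ]
        cand <- get0(key(tailp[1], tailp[2]), envir = ends,
                     ifnotfound = integer())
        cand <- cand[!used[cand]]
        if (length(cand) == 0L) break
        s <- cand[1L]
        used[s] <- TRUE
        nxt <- if (isTRUE(all.equal(segs[s, 1:2], tailp, tolerance = 1e-8)))
          segs[s, 3:4] else segs[s, 1:2]
        pts <- rbind(pts, nxt)
      }
    }
    dimnames(pts) <- list(NULL, c("x", "y"))
    out[[length(out) + 1L]] <- pts
  }
  out
}

#' Compute contour polylines of a matrix
#'
#' Marching squares with linear interpolation of the level crossing on each
#' cell edge; saddle cells are disambiguated by the cell-centre average.
#' Segments are chained into polylines. Coordinates are fractional 0-based
#' point units (`x` = column, `y` = row).
#'
#' @param matrix numeric matrix
#' @param levels an [new_levels()] spec or a numeric vector of level values
#' @return a list (one element per level) of lists of polyline matrices
#'   with columns `x`, `y`; a level above the matrix maximum yields an
#'   empty list
#' @export
compute_contours <- function(matrix, levels) {
  if (!all(is.finite(matrix))) nmr_stop("matrix must be finite")
  vals <- if (inherits(levels, "nmr_levels")) level_values(levels, max(matrix))
          else as.numeric(levels)
  out <- lapply(vals, function(lv) chain_segments(ms_segments(matrix, lv)))
  names(out) <- sprintf("%.8g", vals)
  attr(out, "levels") <- vals
  out
}

#' 1D cross-section of a spectrum
#'
#' Nearest row or column, no interpolation. `axis` names the dimension the
#' trace runs along: a `"direct"` cross-section is taken at an indirect
#' position `at_ppm`, and vice versa.
#'
#' @param spectrum an `nmr_spectrum`
#' @param axis `"direct"` or `"indirect"`
#' @param at_ppm position on the other axis
#' @return data frame with columns `ppm`, `value`
#' @export
cross_section <- function(spectrum, axis = c("direct", "indirect"), at_ppm) {
  axis <- match.arg(axis)
  m <- plane_matrix(spectrum, 1L)
  other <- if (axis == "direct") spectrum$axis_indirect else spectrum$axis_direct
  pt <- ppm_to_pt(other, at_ppm)
  if (pt < -0.5 || pt > other$n_points - 0.5)
    nmr_stop("at_ppm ", at_ppm, " outside the ", setdiff(c("direct",
             "indirect"), axis), " axis span")
  i <- as.integer(round(pt)) + 1L
  if (axis == "direct")
    data.frame(ppm = axis_ppm(spectrum$axis_direct), value = m[i, ])
  else
    data.frame(ppm = axis_ppm(spectrum$axis_indirect), value = m[, i])
}

#' 1D projection of a spectrum
#'
#' Collapses the other dimension by `max` or `sum` of the real matrix.
#'
#' @inheritParams cross_section
#' @param method `"max"` or `"sum"`
#' @return data frame with columns `ppm`, `value`
#' @export
projection <- function(spectrum, axis = c("direct", "indirect"),
                       method = c("max", "sum")) {
  axis <- match.arg(axis); method <- match.arg(method)
  m <- plane_matrix(spectrum, 1L)
  f <- if (method == "max") max else sum
  if (axis == "direct")
    data.frame(ppm = axis_ppm(spectrum$axis_direct),
               value = apply(m, 2L, f))
  else
    data.frame(ppm = axis_ppm(spectrum$axis_indirect),
               value = apply(m, 1L, f))
}

#' Build one overlay item
#'
#' @param spectrum an `nmr_spectrum`
#' @param ref_shift_ppm `c(direct, indirect)` chemical-shift reference
#'   offset added to this item's axes
#' @param color stroke colour
#' @param z_order drawing order (ascending; must be unique in an overlay)
#' @param levels optional [new_levels()] or numeric levels (default:
#'   [default_levels()])
#' @export
overlay_item <- function(spectrum, ref_shift_ppm = c(0, 0), color = "black",
                         z_order = 1L, levels = NULL) {
  structure(list(spectrum = spectrum, ref_shift_ppm = ref_shift_ppm,
                 color = color, z_order = as.integer(z_order),
                 levels = levels), class = "nmr_overlay_item")
}

# greedy label placement: try displacements around the anchor until the
# bounding box clears every previously placed box
place_labels <- function(px, py, texts, char_w = 7, char_h = 12) {
  boxes <- list(); out <- data.frame(x = numeric(), y = numeric(),
                                     text = character())
  offsets <- expand.grid(dx = c(0, 1, -1, 2, -2, 3, -3) * 1.2,
                         dy = c(-1, 1, -2, 2, 0, -3, 3))
  offsets <- offsets[order(abs(offsets$dx) + abs(offsets$dy)), ]
  for (i in seq_along(px)) {
    w <- char_w * nchar(texts[i]); h <- char_h
    placed <- FALSE
    for (o in seq_len(nrow(offsets))) {
      x <- px[i] + offsets$dx[o] * char_w; y <- py[i] + offsets$dy[o] * char_h
      box <- c(x - w / 2, y - h / 2, x + w / 2, y + h / 2)
      clash <- any(vapply(boxes, function(b)
        box[1] < b[3] && box[3] > b[1] && box[2] < b[4] && box[4] > b[2],
        TRUE))
      if (!clash) {
        boxes[[length(boxes) + 1L]] <- box
        out <- rbind(out, data.frame(x = x, y = y, text = texts[i]))
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      x <- px[i]; y <- py[i] - length(boxes) * char_h
      boxes[[length(boxes) + 1L]] <- c(x - w / 2, y - h / 2, x + w / 2, y + h / 2)
      out <- rbind(out, data.frame(x = x, y = y, text = texts[i]))
    }
  }
  out
}

svg_num <- function(x) sprintf("%.3f", x)

#' Render a contour overlay of one or more spectra
#'
#' Items are drawn in ascending z-order; each item's reference shift is a
#' pure ppm offset on its axes. Both ppm axes are reversed (downfield left,
#' downfield bottom). Peak labels are placed greedily to avoid bounding-box
#' overlap. SVG output is written by a deterministic built-in writer (same
#' inputs give byte-identical files); PNG uses the R graphics device.
#'
#' @param items list of [overlay_item()]s (>= 1)
#' @param labels optional `nmr_peaks` whose labels are drawn
#' @param out_path output file
#' @param format `"svg"` or `"png"` (default from the file extension)
#' @param xlim,ylim ppm windows `c(lo, hi)`; default spans all items
#' @param width,height canvas size in pixels
#' @return `out_path`, invisibly
#' @export
render_overlay <- function(items, labels = NULL, out_path,
                           format = tools::file_ext(out_path),
                           xlim = NULL, ylim = NULL,
                           width = 800, height = 600) {
  if (length(items) == 0L) nmr_stop("need at least one overlay item")
  zo <- vapply(items, function(it) it$z_order, 0L)
  if (anyDuplicated(zo)) nmr_stop("z_order values must be unique")
  items <- items[order(zo)]
  rng <- function(which_axis, k) {
    unlist(lapply(items, function(it)
      range(axis_ppm(it$spectrum[[which_axis]]) + it$ref_shift_ppm[k])))
  }
  xlim <- xlim %||% range(rng("axis_direct", 1))
  ylim <- ylim %||% range(rng("axis_indirect", 2))
  xlim <- sort(xlim); ylim <- sort(ylim)
  x_px <- function(ppm) (xlim[2] - ppm) / (xlim[2] - xlim[1]) * width
  y_px <- function(ppm) (ppm - ylim[1]) / (ylim[2] - ylim[1]) * height
  elems <- character()
  for (it in items) {
    m <- plane_matrix(it$spectrum, 1L)
    lv <- it$levels %||% default_levels(it$spectrum)
    cont <- compute_contours(m, lv)
    for (level in cont) for (pl in level) {
      ppm_x <- pt_to_ppm(it$spectrum$axis_direct, pl[, "x"]) +
        it$ref_shift_ppm[1]
      ppm_y <- pt_to_ppm(it$spectrum$axis_indirect, pl[, "y"]) +
        it$ref_shift_ppm[2]
      pts <- paste(svg_num(x_px(ppm_x)), svg_num(y_px(ppm_y)), sep = ",",
                   collapse = " ")
      elems <- c(elems, sprintf(
        '<polyline points="%s" fill="none" stroke="%s" stroke-width="0.8"/>',
        pts, it$color))
    }
  }
  if (!is.null(labels) && nrow(labels) > 0L) {
    lp <- place_labels(x_px(labels$x_ppm), y_px(labels$y_ppm), labels$label)
    elems <- c(elems, sprintf(
      '<text x="%s" y="%s" font-size="11" font-family="monospace" text-anchor="middle" class="peaklabel">%s</text>',
      svg_num(lp$x), svg_num(lp$y), lp$text))
  }
  if (tolower(format) == "svg") {
    write_svg(elems, out_path, width, height)
  } else if (tolower(format) == "png") {
    render_overlay_png(items, labels, out_path, xlim, ylim, width, height)
  } else nmr_stop("unsupported format: ", format)
  invisible(out_path)
}

write_svg <- function(elems, out_path, width, height) {
  ok <- tryCatch({
    con <- file(out_path, "w")
    on.exit(close(con))
    writeLines(c(sprintf(
      '<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d" viewBox="0 0 %d %d">',
      width, height, width, height), elems, "</svg>"), con)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) nmr_stop("I/O error: cannot write ", out_path)
  invisible(out_path)
}

render_overlay_png <- function(items, labels, out_path, xlim, ylim,
                               width, height) {
  if (!capabilities("png")) nmr_stop("png device not available")
  grDevices::png(out_path, width = width, height = height)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(4, 4, 1, 1))
  graphics::plot(NA, xlim = rev(xlim), ylim = rev(ylim),
                 xlab = "direct ppm", ylab = "indirect ppm")
  for (it in items) {
    m <- plane_matrix(it$spectrum, 1L)
    lv <- it$levels %||% default_levels(it$spectrum)
    cont <- compute_contours(m, lv)
    for (level in cont) for (pl in level) {
      graphics::lines(pt_to_ppm(it$spectrum$axis_direct, pl[, "x"]) +
                        it$ref_shift_ppm[1],
                      pt_to_ppm(it$spectrum$axis_indirect, pl[, "y"]) +
                        it$ref_shift_ppm[2], col = it$color)
    }
  }
  if (!is.null(labels) && nrow(labels) > 0L)
    graphics::text(labels$x_ppm, labels$y_ppm, labels$label, cex = 0.7)
  invisible(out_path)
}

# orthographic 3D projection used by the surface renderer
project3d <- function(x, y, z, theta, phi) {
  th <- theta * pi / 180; ph <- phi * pi / 180
  u <- x * cos(th) - y * sin(th)
  v <- x * sin(th) + y * cos(th)
  list(px = u,
       py = -z * cos(ph) + v * sin(ph),
       depth = v * cos(ph) + z * sin(ph))
}

#' Render a 3D surface or terrace view of a spectrum
#'
#' A static orthographic rendering with height-mapped colour, drawn
#' back-to-front into a deterministic SVG (or the PNG device). `surface`
#' overlays contour lines on the continuous mesh; `terrace` quantizes
#' heights to the contour levels, producing stacked slabs. Matrices larger
#' than `max_mesh` points per side are downsampled with a logged note.
#'
#' @param spectrum an `nmr_spectrum` or matrix
#' @param mode `"surface"` or `"terrace"`
#' @param theta,phi view angles in degrees (azimuth, elevation)
#' @param out_path output file (`.svg` or `.png`)
#' @param max_mesh downsampling threshold (points per side)
#' @return `out_path`, invisibly
#' @export
render_surface <- function(spectrum, mode = c("surface", "terrace"),
                           theta = 35, phi = 30, out_path,
                           max_mesh = 1024L) {
  mode <- match.arg(mode)
  m <- if (inherits(spectrum, "nmr_spectrum")) plane_matrix(spectrum, 1L)
       else as.matrix(spectrum)
  step <- max(1L, ceiling(max(dim(m)) / max_mesh))
  if (step > 1L) {
    nmr_log("downsampling ", nrow(m), "x", ncol(m), " matrix by ", step,
            " for meshing")
    m <- m[seq(1L, nrow(m), by = step), seq(1L, ncol(m), by = step)]
  }
  lv <- level_values(default_levels(m), max(m))
  zs <- if (mode == "terrace") {
    q <- matrix(0, nrow(m), ncol(m))
    for (l in lv) q[m >= l] <- l
    q
  } else m
  nr <- nrow(zs); nc <- ncol(zs)
  xs <- (seq_len(nc) - 1) / max(1L, nc - 1L)
  ys <- (seq_len(nr) - 1) / max(1L, nr - 1L)
  zmax <- max(abs(zs), 1e-300)
  zn <- zs / zmax * 0.35
  quads <- list()
  for (i in seq_len(nr - 1L)) for (j in seq_len(nc - 1L)) {
    qx <- xs[c(j, j + 1L, j + 1L, j)]
    qy <- ys[c(i, i, i + 1L, i + 1L)]
    qz <- c(zn[i, j], zn[i, j + 1L], zn[i + 1L, j + 1L], zn[i + 1L, j])
    pr <- project3d(qx, qy, qz, theta, phi)
    quads[[length(quads) + 1L]] <- list(
      px = pr$px, py = pr$py, depth = mean(pr$depth), zmean = mean(qz))
  }
  quads <- quads[order(vapply(quads, function(q) q$depth, 0))]
  shade <- function(z) {
    t <- pmin(1, pmax(0, z / 0.35))
    sprintf("#%02x%02x%02x", round(40 + 180 * t), round(60 + 120 * (1 - t)),
            round(200 - 160 * t))
  }
  all_px <- unlist(lapply(quads, function(q) q$px))
  all_py <- unlist(lapply(quads, function(q) q$py))
  W <- 640; H <- 480
  sx <- function(x) (x - min(all_px)) / diff(range(all_px)) * (W - 40) + 20
  sy <- function(y) (y - min(all_py)) / diff(range(all_py)) * (H - 40) + 20
  elems <- vapply(quads, function(q) sprintf(
    '<polygon points="%s" fill="%s" stroke="#333333" stroke-width="0.15"/>',
    paste(svg_num(sx(q$px)), svg_num(sy(q$py)), sep = ",", collapse = " "),
    shade(q$zmean)), "")
  if (mode == "surface") {
    cont <- compute_contours(zn, lv / zmax * 0.35)
    for (level_i in seq_along(cont)) for (pl in cont[[level_i]]) {
      cx <- approx(seq_along(xs) - 1, xs, pl[, "x"], rule = 2)$y
      cy <- approx(seq_along(ys) - 1, ys, pl[, "y"], rule = 2)$y
      pr <- project3d(cx, cy, attr(cont, "levels")[level_i], theta, phi)
      elems <- c(elems, sprintf(
        '<polyline points="%s" fill="none" stroke="#ffffff" stroke-width="0.5"/>',
        paste(svg_num(sx(pr$px)), svg_num(sy(pr$py)), sep = ",",
              collapse = " ")))
    }
  }
  fmt <- tolower(tools::file_ext(out_path))
  if (fmt == "png") {
    if (!capabilities("png")) nmr_stop("png device not available")
    grDevices::png(out_path, width = W, height = H)
    on.exit(grDevices::dev.off())
    graphics::par(mar = c(0, 0, 0, 0))
    graphics::plot(NA, xlim = c(0, W), ylim = c(H, 0), axes = FALSE,
                   xlab = "", ylab = "")
    for (q in quads)
      graphics::polygon(sx(q$px), sy(q$py), col = shade(q$zmean),
                        border = "#333333")
  } else {
    write_svg(elems, out_path, W, H)
  }
  invisible(out_path)
}
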