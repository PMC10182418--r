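#' Specify a synthetic rod-cell shape
#'
#' Defines an analytic rod-cell outline: a cylinder of mid-cell width
#' `width_um` with elliptical end caps, optionally perturbed by a smooth
#' low-frequency width wobble (so the shape deviates from a perfect
#' spherocylinder, as real cells do) and bent along a circular arc.
#'
#' @param length_um total tip-to-tip length L in micrometres.
#' @param width_um mid-cell width 2r in micrometres; must be `< length_um`.
#' @param cap_aspect cap elongation in `[0, 1]`: 1 gives hemispherical
#'   caps (axial cap extent = r), 0 gives flat ends (a rectangle profile).
#' @param width_wobble relative amplitude (< 0.2) of a smooth width
#'   perturbation made of 1-3 low-order cosine modes along the axis.
#' @param bend_curvature curvature of the cell midline in 1/um (0 =
#'   straight). Bent shapes are for robustness probes only; their ground
#'   truth is defined along the arc-length midline.
#' @param seed RNG seed controlling the wobble modes; the generator is a
#'   pure function of (spec, seed).
#' @return an object of class `"shape_spec"`.
#' @export
shape_spec <- function(length_um, width_um, cap_aspect = 1,
                       width_wobble = 0, bend_curvature = 0, seed = 1L) {
  if (!(length_um > width_um && width_um > 0))
    stop("need length_um > width_um > 0")
  if (cap_aspect < 0 || cap_aspect > 1) stop("cap_aspect must be in [0, 1]")
  if (width_wobble < 0 || width_wobble >= 0.2)
    stop("width_wobble must be in [0, 0.2)")
  if (abs(bend_curvature) * length_um >= pi)
    stop("bend_curvature too strong for this length")
  wob <- NULL
  if (width_wobble > 0) {
    wob <- with_local_seed(seed, {
      m <- sample(1:3, 1L)
      list(k = sample(1:3, m), amp = stats::runif(m, 0.3, 1),
           phase = stats::runif(m, 0, 2 * pi))
    })
  }
  structure(list(length_um = length_um, width_um = width_um,
                 cap_aspect = cap_aspect, width_wobble = width_wobble,
                 bend_curvature = bend_curvature, seed = as.integer(seed),
                 wobble_modes = wob),
            class = "shape_spec")
}

# Evaluate RNG-dependent code under a given seed without disturbing the
# caller's RNG stream.
with_local_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Analytic half-width h(x) of the shape along the (unbent) axis, x in
# [0, L]. Vectorised.
shape_half_width <- function(spec, x) {
  r <- spec$width_um / 2
  len <- spec$length_um
  a <- spec$cap_aspect * r
  h <- rep(r, length(x))
  if (a > 0) {
    lo <- x < a
    hi <- x > len - a
    h[lo] <- r * sqrt(pmax(0, 1 - ((a - x[lo]) / a)^2))
    h[hi] <- r * sqrt(pmax(0, 1 - ((x[hi] - (len - a)) / a)^2))
  }
  h[x < 0 | x > len] <- 0
  if (!is.null(spec$wobble_modes)) {
    wm <- spec$wobble_modes
    g <- rep(0, length(x))
    for (j in seq_along(wm$k))
      g <- g + wm$amp[j] * cos(wm$k[j] * pi * x / len + wm$phase[j])
    gmax <- max(abs(g), 1e-12)
    h <- h * (1 + spec$width_wobble * g / gmax)
  }
  h
}

# Ground-truth geometry by high-resolution quadrature of the slice-formula
# limits: V = int pi h^2 dx, S = int 2 pi h dx, w = (1/L) int 2 h dx.
shape_truth <- function(spec, n_quad = 200001L) {
  len <- spec$length_um
  x <- seq(0, len, length.out = n_quad)
  h <- shape_half_width(spec, x)
  dx <- len / (n_quad - 1L)
  trap <- function(f) (sum(f) - (f[1L] + f[n_quad]) / 2) * dx
  v <- pi * trap(h^2)
  s <- 2 * pi * trap(h)
  list(length = len, width = s / (pi * len), surface = s, volume = v,
       sv_ratio = s / v)
}

#' Generate a synthetic cell contour with known geometry
#'
#' Samples a polygon from the analytic rod-cell outline of a
#' [shape_spec()] and computes its ground-truth geometry (the continuum
#' limits of the slice formulas, `V = int (pi/4) w(x)^2 dx` and
#' `S = int pi w(x) dx`) by high-resolution quadrature of the analytic
#' width profile.
#'
#' @param spec a [shape_spec()].
#' @param n_points number of polygon vertices (cosine-spaced along the
#'   axis so the caps are densely sampled).
#' @param n_quad quadrature resolution for the ground truth.
#' @return list with `contour` (a [contour()], axis-aligned starting at
#'   x = 0), `truth` (list: length, width, surface, volume, sv_ratio) and
#'   `spec`.
#' @export
make_contour <- function(spec, n_points = 400L, n_quad = 200001L) {
  stopifnot(inherits(spec, "shape_spec"))
  len <- spec$length_um
  n_half <- ceiling(n_points / 2)
  q <- seq(0, 1, length.out = n_half)
  x <- len / 2 * (1 - cos(pi * q))          # clustered at both tips
  h <- shape_half_width(spec, x)
  top <- cbind(x, h)
  bot <- cbind(rev(x), -rev(h))
  # drop duplicated tip points where h == 0
  pts <- rbind(top, bot)
  keep <- c(TRUE, rowSums(abs(diff(pts))) > 1e-12)
  pts <- pts[keep, , drop = FALSE]
  if (all(abs(pts[nrow(pts), ] - pts[1L, ]) < 1e-12))
    pts <- pts[-nrow(pts), , drop = FALSE]
  if (spec$bend_curvature != 0) {
    k <- spec$bend_curvature
    th <- (pts[, 1L] - len / 2) * k
    mx <- len / 2 + sin(th) / k
    my <- (1 - cos(th)) / k
    pts <- cbind(mx - pts[, 2L] * sin(th), my + pts[, 2L] * cos(th))
  }
  list(contour = contour(pts, check = FALSE),
       truth = shape_truth(spec, n_quad = n_quad),
       spec = spec)
}

#' Specify how a synthetic cell is rendered to images
#'
#' @param pixel_size_um physical pixel size in micrometres.
#' @param image_shape integer (rows, cols), or `NULL` to size the frame
#'   automatically so the cell has at least `margin_um` of clearance.
#' @param noise_sd Gaussian noise standard deviation added to the
#'   brightfield and marker channels (intensity units; channels are ~[0, 1]).
#' @param septum if `TRUE`, paint a bright septum band (0.5 um wide,
#'   perpendicular to the axis at mid-length) into the marker channel,
#'   emulating a septum-localised fluorescent stain in a dividing cell.
#' @param septum_contrast ratio of septum-band marker intensity to the
#'   off-band baseline; the achievable selection signal-to-noise.
#' @param margin_um frame clearance around the cell.
#' @param seed RNG seed for the rendering noise.
#' @return an object of class `"render_spec"`.
#' @export
render_spec <- function(pixel_size_um = 0.1, image_shape = NULL,
                        noise_sd = 0, septum = FALSE, septum_contrast = 10,
                        margin_um = 2, seed = 1L) {
  if (pixel_size_um <= 0) stop("pixel_size_um must be positive")
  if (septum_contrast < 1) stop("septum_contrast must be >= 1")
  structure(list(pixel_size_um = pixel_size_um, image_shape = image_shape,
                 noise_sd = noise_sd, septum = septum,
                 septum_contrast = septum_contrast, margin_um = margin_um,
                 seed = as.integer(seed)),
            class = "render_spec")
}

# Scanline polygon fill on the pixel-centre grid. Pixel centre (row r,
# col c) sits at ((c-1)*px, (r-1)*px); row -> y, col -> x, origin
# top-left.
rasterize_polygon <- function(pts, nrow_px, ncol_px, pixel_size_um) {
  mask <- matrix(0L, nrow_px, ncol_px)
  x1 <- pts[, 1L]; y1 <- pts[, 2L]
  x2 <- c(x1[-1L], x1[1L]); y2 <- c(y1[-1L], y1[1L])
  ys <- (seq_len(nrow_px) - 1L) * pixel_size_um
  for (r in seq_len(nrow_px)) {
    y <- ys[r]
    crossing <- (y1 > y) != (y2 > y)
    if (!any(crossing)) next
    xc <- x1[crossing] +
      (y - y1[crossing]) / (y2[crossing] - y1[crossing]) *
      (x2[crossing] - x1[crossing])
    xc <- sort(xc)
    for (j in seq(1L, length(xc) - 1L, by = 2L)) {
      c0 <- ceiling(xc[j] / pixel_size_um - 1e-9) + 1L
      c1 <- floor(xc[j + 1L] / pixel_size_um + 1e-9) + 1L
      if (c1 >= c0) {
        c0 <- max(c0, 1L); c1 <- min(c1, ncol_px)
        if (c1 >= c0) mask[r, c0:c1] <- 1L
      }
    }
  }
  mask
}

#' Render a synthetic cell to mask, brightfield-like and marker images
#'
#' The mask channel is the exact polygon rasterisation on the pixel-centre
#' grid. The brightfield-like channel is a grey background with a smoothed
#' dark halo at the mask edge plus Gaussian noise. The marker channel has
#' a baseline cytoplasmic/background level and, when `render$septum` is
#' `TRUE`, a bright band 0.5 um wide perpendicular to the cell axis at
#' mid-length.
#'
#' @param ct a [contour()] (e.g. from [make_contour()]).
#' @param render a [render_spec()].
#' @return list with `mask`, `brightfield`, `marker` (matrices, row = y,
#'   col = x), `contour` (the contour translated into the frame),
#'   `pixel_size_um` and `placed_offset_um`.
#' @export
render_cell <- function(ct, render = render_spec()) {
  ct <- as_contour(ct)
  px <- render$pixel_size_um
  pts <- ct$points
  bb_min <- apply(pts, 2L, min)
  bb_max <- apply(pts, 2L, max)
  if (is.null(render$image_shape)) {
    offset <- render$margin_um - bb_min
    extent <- bb_max - bb_min + 2 * render$margin_um
    ncol_px <- ceiling(extent[1L] / px) + 1L
    nrow_px <- ceiling(extent[2L] / px) + 1L
  } else {
    nrow_px <- render$image_shape[1L]
    ncol_px <- render$image_shape[2L]
    frame <- c((ncol_px - 1L) * px, (nrow_px - 1L) * px)
    offset <- (frame - (bb_max - bb_min)) / 2 - bb_min
    if (any(bb_max - bb_min + 2 * render$margin_um > frame))
      stop("cell does not fit in the image frame with the required margin")
  }
  pts <- sweep(pts, 2L, offset, "+")
  placed <- contour(pts, check = FALSE)
  mask <- rasterize_polygon(pts, nrow_px, ncol_px, px)

  with_local_seed(render$seed, {
    sigma <- max(1, 0.15 / px)
    bm <- EBImage::gblur(mask, sigma = sigma)
    edge <- 4 * bm * (1 - bm)
    brightfield <- 0.8 - 0.45 * edge
    if (render$noise_sd > 0)
      brightfield <- brightfield +
        matrix(stats::rnorm(length(mask), sd = render$noise_sd),
               nrow_px, ncol_px)

    baseline <- 0.1
    marker <- matrix(baseline, nrow_px, ncol_px)
    if (render$septum) {
      axis <- estimate_axis(placed)
      len <- as.numeric(cell_length(axis))
      inside <- which(mask == 1L)
      rr <- (inside - 1L) %% nrow_px + 1L
      cc <- (inside - 1L) %/% nrow_px + 1L
      sx <- (cc - 1L) * px - axis$origin[1L]
      sy <- (rr - 1L) * px - axis$origin[2L]
      s <- sx * axis$direction[1L] + sy * axis$direction[2L]
      mid <- mean(axis$proj_range)
      band <- abs(s - mid) <= 0.25
      marker[inside[band]] <- baseline * render$septum_contrast
    }
    if (render$noise_sd > 0)
      marker <- marker +
        matrix(stats::rnorm(length(mask), sd = render$noise_sd),
               nrow_px, ncol_px)

    list(mask = mask, brightfield = brightfield, marker = marker,
         contour = placed, pixel_size_um = px, placed_offset_um = offset)
  })
}

#' Render a field of several synthetic cells into one image set
#'
#' Cells are laid out on a grid with clearance so they never touch; used
#' to exercise multi-cell extraction and septum-based selection.
#'
#' @param cells list of entries from [make_contour()].
#' @param septum logical vector: which cells carry a septum band.
#' @param pixel_size_um,noise_sd,septum_contrast see [render_spec()].
#' @param seed RNG seed for noise.
#' @return list with `mask`, `brightfield`, `marker`, `pixel_size_um`,
#'   `contours` (placed per-cell contours) and `septum` (the labels).
#' @export
render_field <- function(cells, septum, pixel_size_um = 0.1,
                         noise_sd = 0, septum_contrast = 10, seed = 1L) {
  stopifnot(length(cells) == length(septum))
  n <- length(cells)
  ncols <- ceiling(sqrt(n))
  nrows <- ceiling(n / ncols)
  spans <- vapply(cells, function(cl) {
    p <- cl$contour$points
    c(diff(range(p[, 1L])), diff(range(p[, 2L])))
  }, numeric(2L))
  cw <- max(spans[1L, ]) + 4
  ch <- max(spans[2L, ]) + 4
  px <- pixel_size_um
  nrow_px <- ceiling(nrows * ch / px) + 1L
  ncol_px <- ceiling(ncols * cw / px) + 1L
  mask <- matrix(0L, nrow_px, ncol_px)
  marker <- matrix(0.1, nrow_px, ncol_px)
  contours <- vector("list", n)
  for (i in seq_len(n)) {
    gr <- (i - 1L) %/% ncols
    gc <- (i - 1L) %% ncols
    pts <- cells[[i]]$contour$points
    ctr <- c(gc * cw + cw / 2, gr * ch + ch / 2)
    pts <- sweep(pts, 2L, ctr - (apply(pts, 2L, min) + spans[, i] / 2), "+")
    placed <- contour(pts, check = FALSE)
    contours[[i]] <- placed
    sub <- rasterize_polygon(pts, nrow_px, ncol_px, px)
    mask[sub == 1L] <- 1L
    if (septum[i]) {
      axis <- estimate_axis(placed)
      inside <- which(sub == 1L)
      rr <- (inside - 1L) %% nrow_px + 1L
      cc <- (inside - 1L) %/% nrow_px + 1L
      s <- ((cc - 1L) * px - axis$origin[1L]) * axis$direction[1L] +
           ((rr - 1L) * px - axis$origin[2L]) * axis$direction[2L]
      band <- abs(s - mean(axis$proj_range)) <= 0.25
      marker[inside[band]] <- 0.1 * septum_contrast
    }
  }
  with_local_seed(seed, {
    sigma <- max(1, 0.15 / px)
    bm <- EBImage::gblur(mask, sigma = sigma)
    brightfield <- 0.8 - 0.45 * (4 * bm * (1 - bm))
    if (noise_sd > 0) {
      brightfield <- brightfield +
        matrix(stats::rnorm(length(mask), sd = noise_sd), nrow_px, ncol_px)
      marker <- marker +
        matrix(stats::rnorm(length(mask), sd = noise_sd), nrow_px, ncol_px)
    }
    list(mask = mask, brightfield = brightfield, marker = marker,
         pixel_size_um = px, contours = contours, septum = septum)
  })
}
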