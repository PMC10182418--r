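#' Estimate the long axis of a cell contour
#'
#' The axis direction is the first principal axis of the contour's enclosed
#' region, computed from area-weighted second central moments of the
#' polygon (so the result does not depend on how densely the outline is
#' digitised). The two extremities are the contour vertices with minimal
#' and maximal projection onto that direction.
#'
#' @param ct a [contour()].
#' @return an object of class `"axis_frame"`: list with `origin` (area
#'   centroid), `direction` (unit 2-vector), `extremity_a`, `extremity_b`
#'   (contour points at minimal/maximal projection), and `proj_range`
#'   (projection span endpoints relative to `origin`).
#' @export
estimate_axis <- function(ct) {
  ct <- as_contour(ct)
  m <- polygon_moments(ct$points)
  if (abs(m$area) < 1e-12) stop("degenerate contour: zero enclosed area")
  eig <- eigen(m$cov, symmetric = TRUE)
  if (eig$values[1L] < 1e-12)
    stop("degenerate contour: collinear points (no principal axis)")
  u <- eig$vectors[, 1L]
  # canonical sign: positive x, break ties with positive y
  if (u[1L] < 0 || (abs(u[1L]) < 1e-12 && u[2L] < 0)) u <- -u
  proj <- (ct$points[, 1L] - m$centroid[1L]) * u[1L] +
          (ct$points[, 2L] - m$centroid[2L]) * u[2L]
  ia <- which.min(proj); ib <- which.max(proj)
  structure(list(origin = m$centroid, direction = u,
                 extremity_a = ct$points[ia, ],
                 extremity_b = ct$points[ib, ],
                 proj_range = c(proj[ia], proj[ib])),
            class = "axis_frame")
}

#' Cell length from an axis frame
#'
#' Length is the span of the contour's projections onto the principal
#' axis (tip-to-tip extent along the length axis). For straight cells this
#' equals the Euclidean distance between the two extremities, which is
#' returned as attribute `"tip_to_tip"` for comparison on bent cells.
#'
#' @param axis an `"axis_frame"` from [estimate_axis()].
#' @return length in micrometres, with attribute `tip_to_tip`.
#' @export
cell_length <- function(axis) {
  stopifnot(inherits(axis, "axis_frame"))
  len <- diff(axis$proj_range)
  attr(len, "tip_to_tip") <-
    sqrt(sum((axis$extremity_b - axis$extremity_a)^2))
  len
}

#' Slice a contour into width segments perpendicular to the long axis
#'
#' The projection span `[0, L]` along the axis is partitioned into
#' `n_segments` slabs of equal height `d = L / n_segments`. The width
#' `w_i` of segment i is measured where the segment's centre line
#' (perpendicular to the axis at `s_i = (i - 1/2) d`) crosses the
#' contour: the extent (max minus min) of the perpendicular coordinate
#' over the exact polygon-edge crossings with that line. The contour is
#' resampled to uniform arc-length spacing first so the crossings are
#' insensitive to the original vertex density. Slabs whose centre line
#' yields fewer than two crossings (possible only for degenerate or
#' numerically touching outlines) fall back to the extent of the
#' resampled vertices falling inside the slab, and failing that to linear
#' interpolation from neighbouring slabs; terminal slabs with no
#' information get width 0.
#'
#' @param ct a [contour()].
#' @param axis an `"axis_frame"`; computed from `ct` when missing.
#' @param n_segments number of slabs N (default 50).
#' @param resample_to number of vertices for uniform arc-length resampling
#'   before slicing; default `max(4 * n_segments, 400)`.
#' @return an object of class `"width_profile"`: list with `n_segments`,
#'   `widths` (length N, micrometres), `slice_height` (`d = L/N`) and
#'   `length` (L).
#' @export
slice_widths <- function(ct, axis = NULL, n_segments = 50L,
                         resample_to = NULL) {
  ct <- as_contour(ct)
  if (is.null(axis)) axis <- estimate_axis(ct)
  n_segments <- as.integer(n_segments)
  if (n_segments < 2L) stop("n_segments must be at least 2")
  if (is.null(resample_to)) resample_to <- max(4L * n_segments, 400L)
  if (resample_to < n_segments)
    stop("resampled contour has fewer points than slabs")
  rs <- resample_contour(ct, resample_to)$points

  u <- axis$direction
  v <- c(-u[2L], u[1L])
  rel <- sweep(rs, 2L, axis$origin)
  s <- as.numeric(rel %*% u)
  t <- as.numeric(rel %*% v)
  s <- s - min(s)
  len <- max(s)
  d <- len / n_segments

  sn <- c(s[-1L], s[1L]); tn <- c(t[-1L], t[1L])
  w <- rep(NA_real_, n_segments)
  for (k in seq_len(n_segments)) {
    b <- (k - 0.5) * d
    hit <- (s - b) * (sn - b) < 0
    tc <- t[hit] + (b - s[hit]) / (sn[hit] - s[hit]) * (tn[hit] - t[hit])
    on_line <- abs(s - b) < 1e-12 * max(len, 1)
    tc <- c(tc, t[on_line])
    if (length(tc) >= 2L) w[k] <- max(tc) - min(tc)
  }

  if (anyNA(w)) {
    # fallback: extent of resampled vertices inside each starved slab
    idx <- pmin(pmax(floor(s / d) + 1L, 1L), n_segments)
    for (k in which(is.na(w))) {
      tk <- t[idx == k]
      if (length(tk) >= 2L) w[k] <- max(tk) - min(tk)
    }
  }
  if (anyNA(w)) {
    filled <- which(!is.na(w))
    if (!length(filled)) stop("no contour crossings found in any slab")
    empty <- which(is.na(w))
    interior <- empty[empty > min(filled) & empty < max(filled)]
    terminal <- setdiff(empty, interior)
    if (length(interior))
      w[interior] <- stats::approx(filled, w[filled], xout = interior)$y
    w[terminal] <- 0
  }
  w[w < 0] <- 0

  structure(list(n_segments = n_segments, widths = as.numeric(w),
                 slice_height = d, length = len),
            class = "width_profile")
}

#' Mean cell width from a width profile
#'
#' The arithmetic mean of the per-slice widths, `w = (1/N) * sum(w_i)`.
#'
#' @param profile a `"width_profile"` from [slice_widths()].
#' @return mean width in micrometres.
#' @export
mean_width <- function(profile) {
  stopifnot(inherits(profile, "width_profile"))
  mean(profile$widths)
}

#' Cell volume from a width profile
#'
#' Each slice is treated as a cylinder of diameter `w_i` and height
#' `d = L/N` (rotational symmetry per segment):
#' `V = sum_i (pi/4) * d * w_i^2`. No cap or slant corrections are
#' applied.
#'
#' @inheritParams mean_width
#' @return volume in cubic micrometres.
#' @export
cell_volume <- function(profile) {
  stopifnot(inherits(profile, "width_profile"))
  sum(pi / 4 * profile$slice_height * profile$widths^2)
}

#' Cell surface area from a width profile
#'
#' The lateral area of the stacked cylinders, `S = sum_i pi * d * w_i`.
#' This is the standard slice approximation used alongside
#' [cell_volume()]; it omits the slant factor of a true surface of
#' revolution (see [surface_revolution()] for the slant-corrected
#' diagnostic).
#'
#' @inheritParams mean_width
#' @return surface area in square micrometres.
#' @export
cell_surface <- function(profile) {
  stopifnot(inherits(profile, "width_profile"))
  sum(pi * profile$slice_height * profile$widths)
}

#' Slant-corrected surface of revolution (diagnostic)
#'
#' Frustum-sum approximation of the true surface of revolution of the
#' width profile: lateral areas `pi * (r_i + r_{i+1}) * slant` between
#' successive slice radii, plus disc closures at the two ends when the
#' terminal radii are nonzero. Reported as a diagnostic only; the primary
#' surface output is [cell_surface()].
#'
#' @inheritParams mean_width
#' @return surface area in square micrometres.
#' @export
surface_revolution <- function(profile) {
  stopifnot(inherits(profile, "width_profile"))
  r <- profile$widths / 2
  d <- profile$slice_height
  # radii at slab centres; extend to zero-radius tips half a slab beyond
  rr <- c(0, r, 0)
  dd <- c(d / 2, rep(d, length(r) - 1L), d / 2)
  slant <- sqrt(dd^2 + diff(rr)^2)
  sum(pi * (rr[-length(rr)] + rr[-1L]) * slant)
}

#' Quantify the geometry of a single cell contour
#'
#' Composes [estimate_axis()], [cell_length()], [slice_widths()] and the
#' slice formulas into one per-cell record: length L, mean width w,
#' surface `S = sum(pi d w_i)`, volume `V = sum((pi/4) d w_i^2)` and the
#' surface-to-volume ratio S/V.
#'
#' @param ct a [contour()].
#' @param n_segments number of perpendicular slices N (default 50).
#' @param resample_to see [slice_widths()].
#' @return an object of class `"cell_geometry"`: list with `length`,
#'   `width`, `surface`, `volume`, `sv_ratio`, `surface_slant` (diagnostic
#'   slant-corrected surface), `length_tip_to_tip`, and `profile` (the
#'   `"width_profile"`).
#' @export
quantify_cell <- function(ct, n_segments = 50L, resample_to = NULL) {
  ct <- as_contour(ct)
  axis <- estimate_axis(ct)
  len <- cell_length(axis)
  prof <- slice_widths(ct, axis, n_segments = n_segments,
                       resample_to = resample_to)
  w <- mean_width(prof)
  s <- cell_surface(prof)
  v <- cell_volume(prof)
  if (w > as.numeric(len))
    warning("cell is wider than long; not a rod-shaped cell?")
  structure(list(length = as.numeric(len), width = w, surface = s,
                 volume = v, sv_ratio = s / v,
                 surface_slant = surface_revolution(prof),
                 length_tip_to_tip = attr(len, "tip_to_tip"),
                 profile = prof),
            class = "cell_geometry")
}

#' @export
print.cell_geometry <- function(x, ...) {
  cat(sprintf(paste0("<cell_geometry: L = %.3f um, w = %.3f um, ",
                     "S = %.2f um^2, V = %.2f um^3, S/V = %.3f /um>\n"),
              x$length, x$width, x$surface, x$volume, x$sv_ratio))
  invisible(x)
}

#' Quantify a list of contours into a per-cell table
#'
#' @param contours named list of [contour()] objects (names become
#'   `cell_id`; unnamed lists are numbered).
#' @inheritParams quantify_cell
#' @return data.frame with columns `cell_id`, `length_um`, `width_um`,
#'   `surface_um2`, `volume_um3`, `sv_ratio_per_um`, `n_segments`.
#' @export
quantify_cells <- function(contours, n_segments = 50L) {
  if (inherits(contours, "contour")) contours <- list(contours)
  ids <- names(contours)
  if (is.null(ids)) ids <- sprintf("cell_%03d", seq_along(contours))
  rows <- lapply(seq_along(contours), function(i) {
    g <- quantify_cell(contours[[i]], n_segments = n_segments)
    data.frame(cell_id = ids[i], length_um = g$length, width_um = g$width,
               surface_um2 = g$surface, volume_um3 = g$volume,
               sv_ratio_per_um = g$sv_ratio,
               n_segments = as.integer(n_segments))
  })
  do.call(rbind, rows)
}
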