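#' Construct a cell contour
#'
#' A contour is a closed, ordered polygon (in micrometres) bounding the
#' two-dimensional cross-section of a single cell. The last vertex is
#' implicitly connected to the first; a duplicated closing vertex is
#' dropped.
#'
#' @param points numeric matrix or data.frame with two columns (x, y) in
#'   micrometres, or a numeric vector of x when `y` is given.
#' @param y optional numeric vector of y coordinates.
#' @param check if `TRUE` (default) validate the polygon: at least 8
#'   vertices, finite coordinates, nonzero enclosed area, and (for polygons
#'   of up to 2000 vertices) no self-intersection.
#' @return an object of class `"contour"`: a list with `points` (n x 2
#'   matrix, columns `x`, `y`) and `closed = TRUE`.
#' @export
contour <- function(points, y = NULL, check = TRUE) {
  if (!is.null(y)) points <- cbind(points, y)
  points <- as.matrix(points)
  if (ncol(points) != 2L) stop("contour points must have two columns (x, y)")
  storage.mode(points) <- "double"
  colnames(points) <- c("x", "y")
  n <- nrow(points)
  if (n >= 2L && all(abs(points[n, ] - points[1L, ]) < 1e-12)) {
    points <- points[-n, , drop = FALSE]
    n <- n - 1L
  }
  if (check) {
    if (n < 8L) stop("contour must have at least 8 distinct vertices")
    if (!all(is.finite(points))) stop("contour coordinates must be finite")
    if (abs(polygon_area(points)) < 1e-12)
      stop("contour encloses zero area (degenerate or collinear)")
    if (n <= 2000L && !is_simple_polygon(points))
      stop("contour is self-intersecting; expected a simple polygon")
  }
  structure(list(points = points, closed = TRUE), class = "contour")
}

#' @export
print.contour <- function(x, ...) {
  cat(sprintf("<contour: %d vertices, area %.3f um^2>\n",
              nrow(x$points), abs(polygon_area(x$points))))
  invisible(x)
}

as_contour <- function(x, check = TRUE) {
  if (inherits(x, "contour")) x else contour(x, check = check)
}

# Signed area by the shoelace formula (positive for counter-clockwise).
polygon_area <- function(pts) {
  x <- pts[, 1L]; y <- pts[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  sum(x * yn - xn * y) / 2
}

# Area centroid of a simple polygon.
polygon_centroid <- function(pts) {
  x <- pts[, 1L]; y <- pts[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

# Area, centroid and central second-moment (covariance) matrix of the
# enclosed region, via the standard polygon-moment formulas.
polygon_moments <- function(pts) {
  x <- pts[, 1L]; y <- pts[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  cx <- sum((x + xn) * cr) / (6 * a)
  cy <- sum((y + yn) * cr) / (6 * a)
  ixx <- sum((x^2 + x * xn + xn^2) * cr) / 12          # integral of x^2 dA
  iyy <- sum((y^2 + y * yn + yn^2) * cr) / 12          # integral of y^2 dA
  ixy <- sum((x * yn + 2 * x * y + 2 * xn * yn + xn * y) * cr) / 24
  cov <- matrix(c(ixx / a - cx^2, ixy / a - cx * cy,
                  ixy / a - cx * cy, iyy / a - cy^2), 2L, 2L)
  list(area = a, centroid = c(cx, cy), cov = cov)
}

# O(n^2) segment-intersection test; adjacent edges share endpoints and are
# skipped. Used only at construction time for modest polygon sizes.
is_simple_polygon <- function(pts) {
  n <- nrow(pts)
  x1 <- pts[, 1L]; y1 <- pts[, 2L]
  x2 <- c(x1[-1L], x1[1L]); y2 <- c(y1[-1L], y1[1L])
  orient <- function(ax, ay, bx, by, cx, cy)
    sign((bx - ax) * (cy - ay) - (by - ay) * (cx - ax))
  for (i in seq_len(n - 2L)) {
    j <- (i + 2L):n
    j <- j[!(i == 1L & j == n)]          # edges adjacent to edge i
    if (!length(j)) next
    d1 <- orient(x1[i], y1[i], x2[i], y2[i], x1[j], y1[j])
    d2 <- orient(x1[i], y1[i], x2[i], y2[i], x2[j], y2[j])
    d3 <- orient(x1[j], y1[j], x2[j], y2[j], x1[i], y1[i])
    d4 <- orient(x1[j], y1[j], x2[j], y2[j], x2[i], y2[i])
    if (any(d1 != d2 & d3 != d4 & d1 != 0 & d2 != 0 & d3 != 0 & d4 != 0))
      return(FALSE)
  }
  TRUE
}

#' Resample a contour to uniform arc-length spacing
#'
#' Linear interpolation along the closed polygon perimeter. The original
#' vertices are retained in the output (so corners are never cut), with
#' at least `n_points` uniformly spaced positions added between them.
#' Slicing uses this to make width estimates insensitive to the original
#' vertex density.
#'
#' @param ct a [contour()].
#' @param n_points minimum number of uniformly spaced vertices.
#' @return a `"contour"` with at least `n_points` vertices.
#' @export
resample_contour <- function(ct, n_points) {
  pts <- as_contour(ct)$points
  n <- nrow(pts)
  closed <- rbind(pts, pts[1L, ])
  seg <- sqrt(diff(closed[, 1L])^2 + diff(closed[, 2L])^2)
  s <- c(0, cumsum(seg))
  per <- s[n + 1L]
  if (per <= 0) stop("contour has zero perimeter")
  uniform <- seq(0, per, length.out = n_points + 1L)[-(n_points + 1L)]
  target <- sort(unique(c(uniform, s[-(n + 1L)])))
  target <- target[c(TRUE, diff(target) > 1e-12 * per)]
  xi <- stats::approx(s, closed[, 1L], xout = target, ties = "ordered")$y
  yi <- stats::approx(s, closed[, 2L], xout = target, ties = "ordered")$y
  contour(cbind(xi, yi), check = FALSE)
}

#' Apply a rigid motion (rotation then translation) to a contour
#'
#' Convenience used by the synthetic generator and invariance tests.
#'
#' @param ct a [contour()].
#' @param angle rotation angle in radians, counter-clockwise.
#' @param shift numeric length-2 translation in micrometres.
#' @return the transformed `"contour"`.
#' @export
transform_contour <- function(ct, angle = 0, shift = c(0, 0)) {
  pts <- as_contour(ct)$points
  rot <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2L, 2L)
  contour(sweep(pts %*% t(rot), 2L, shift, "+"), check = FALSE)
}
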