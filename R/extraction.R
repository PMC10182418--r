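#' Segmentation and septum-selection parameters
#'
#' @param threshold_method `"fixed"` (use `threshold_value`) or `"otsu"`
#'   (histogram-based automatic threshold).
#' @param threshold_value intensity threshold for `"fixed"`.
#' @param polarity `"bright"` when cells are brighter than background
#'   (mask channel); `"dark"` when cells appear as dark outlines on a
#'   light background (brightfield-like images; ring interiors are
#'   filled before labelling).
#' @param min_area_um2 minimum object area retained, in square
#'   micrometres.
#' @param smoothing_um Gaussian smoothing scale applied to the image
#'   before thresholding and sub-pixel contour tracing.
#' @param septum_snr_min minimal ratio of mid-cell marker band intensity
#'   to the cell's off-band median for a cell to count as septating.
#' @return an object of class `"segmentation_params"`.
#' @export
segmentation_params <- function(threshold_method = c("fixed", "otsu"),
                                threshold_value = 0.5,
                                polarity = c("bright", "dark"),
                                min_area_um2 = 5,
                                smoothing_um = 0.1,
                                septum_snr_min = 2) {
  threshold_method <- match.arg(threshold_method)
  polarity <- match.arg(polarity)
  if (min_area_um2 <= 0) stop("min_area_um2 must be positive")
  if (septum_snr_min < 1) stop("septum_snr_min must be >= 1")
  structure(list(threshold_method = threshold_method,
                 threshold_value = threshold_value, polarity = polarity,
                 min_area_um2 = min_area_um2, smoothing_um = smoothing_um,
                 septum_snr_min = septum_snr_min),
            class = "segmentation_params")
}

#' Extract per-cell contours from a single-plane image
#'
#' Thresholds the (optionally smoothed) image, labels connected
#' components, discards components below the minimum area or touching the
#' image border, and traces each remaining component's boundary at the
#' threshold level with sub-pixel (marching-squares style, linearly
#' interpolated) iso-contours. Pixel centres sit on an integer grid
#' (row -> y, column -> x, origin top-left); contour coordinates are
#' continuous micrometres.
#'
#' @param image numeric matrix (row = y, col = x).
#' @param pixel_size_um physical pixel size, micrometres per pixel.
#' @param params a [segmentation_params()].
#' @return named list of [contour()] objects (possibly empty); names are
#'   `cell_001`, `cell_002`, ... in label order.
#' @export
extract_contours <- function(image, pixel_size_um,
                             params = segmentation_params()) {
  if (!is.matrix(image)) image <- as.matrix(image)
  if (!all(is.finite(image))) stop("image contains non-finite pixels")
  if (pixel_size_um <= 0) stop("pixel_size_um must be positive")
  px <- pixel_size_um
  nr <- nrow(image); nc <- ncol(image)

  img_s <- image
  if (params$smoothing_um > 0) {
    sigma <- params$smoothing_um / px
    if (sigma >= 0.3) img_s <- EBImage::gblur(image, sigma = sigma)
  }
  work <- if (params$polarity == "dark") max(img_s) - img_s else img_s

  thr <- if (params$threshold_method == "otsu") {
    rng <- range(work)
    if (diff(rng) < 1e-12) return(structure(list(), names = character()))
    rng[1L] + EBImage::otsu(EBImage::Image((work - rng[1L]) / diff(rng))) *
      diff(rng)
  } else if (params$polarity == "dark") {
    max(img_s) - params$threshold_value
  } else {
    params$threshold_value
  }

  binary <- work > thr
  if (params$polarity == "dark")
    binary <- EBImage::fillHull(binary) > 0
  lab <- EBImage::bwlabel(binary)
  nlab <- max(lab)
  if (nlab == 0L) return(structure(list(), names = character()))

  areas <- tabulate(lab[lab > 0L], nbins = nlab) * px^2
  border_labs <- unique(c(lab[1L, ], lab[nr, ], lab[, 1L], lab[, nc]))
  keep <- setdiff(which(areas >= params$min_area_um2), border_labs)

  out <- list()
  for (l in keep) {
    idx <- which(lab == l)
    rr <- range((idx - 1L) %% nr + 1L)
    cc <- range((idx - 1L) %/% nr + 1L)
    r0 <- max(1L, rr[1L] - 3L); r1 <- min(nr, rr[2L] + 3L)
    c0 <- max(1L, cc[1L] - 3L); c1 <- min(nc, cc[2L] + 3L)
    z <- work[r0:r1, c0:c1]
    z[lab[r0:r1, c0:c1] != l & lab[r0:r1, c0:c1] != 0L] <- min(z)
    # contourLines: z[i, j] at (x[i], y[j]); our rows are y, columns x
    cl <- grDevices::contourLines(x = ((r0:r1) - 1L) * px,
                                  y = ((c0:c1) - 1L) * px,
                                  z = z, levels = thr)
    if (!length(cl)) next
    cl <- cl[[which.max(vapply(cl, function(p) length(p$x), numeric(1L)))]]
    pts <- cbind(cl$y, cl$x)                 # back to (x, y)
    if (nrow(pts) < 8L) next
    out[[sprintf("cell_%03d", length(out) + 1L)]] <-
      contour(pts, check = FALSE)
  }
  out
}

#' Score and select septating cells from a marker channel
#'
#' For each contour, marker intensity is averaged over a band 0.5 um wide
#' centred at mid-length (perpendicular to the cell's long axis, spanning
#' the cell width) and compared with the median marker intensity over the
#' rest of the cell interior. Cells whose band-to-background ratio
#' reaches `params$septum_snr_min` are kept — an automated surrogate for
#' manual selection of dividing cells by the intracellular location of a
#' septum stain.
#'
#' @param contours named list of [contour()] objects sharing the marker
#'   image's coordinate frame.
#' @param marker_image numeric matrix (row = y, col = x).
#' @param pixel_size_um micrometres per pixel.
#' @param params a [segmentation_params()].
#' @return list with `kept` (the selected contours), `scores`
#'   (data.frame: `cell_id`, `septum_snr`, `kept` 0/1).
#' @export
select_septated <- function(contours, marker_image, pixel_size_um,
                            params = segmentation_params()) {
  px <- pixel_size_um
  nr <- nrow(marker_image); nc <- ncol(marker_image)
  ids <- names(contours)
  if (is.null(ids)) ids <- sprintf("cell_%03d", seq_along(contours))
  snr <- rep(NA_real_, length(contours))
  for (i in seq_along(contours)) {
    ct <- as_contour(contours[[i]])
    axis <- estimate_axis(ct)
    inside <- which(rasterize_polygon(ct$points, nr, nc, px) == 1L)
    if (length(inside) < 10L) next
    rr <- (inside - 1L) %% nr + 1L
    cc <- (inside - 1L) %/% nr + 1L
    s <- ((cc - 1L) * px - axis$origin[1L]) * axis$direction[1L] +
         ((rr - 1L) * px - axis$origin[2L]) * axis$direction[2L]
    band <- abs(s - mean(axis$proj_range)) <= 0.25
    if (!any(band) || all(band)) next
    bg <- stats::median(marker_image[inside[!band]])
    snr[i] <- mean(marker_image[inside[band]]) / max(bg, 1e-9)
  }
  kept <- !is.na(snr) & snr >= params$septum_snr_min
  list(kept = contours[kept],
       scores = data.frame(cell_id = ids, septum_snr = snr,
                           kept = as.integer(kept)))
}
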