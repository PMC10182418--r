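#' Read cell contours from CSV
#'
#' Expects columns `cell_id`, `vertex_index`, `x_um`, `y_um`; one closed
#' polygon per `cell_id`, vertices ordered by `vertex_index`.
#'
#' @param path CSV file path.
#' @return named list of [contour()] objects.
#' @export
read_contours_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "vertex_index", "x_um", "y_um")
  if (!all(need %in% names(d)))
    stop("contour CSV must have columns: ", paste(need, collapse = ", "))
  parts <- split(d, d$cell_id)
  out <- lapply(parts, function(p) {
    p <- p[order(p$vertex_index), ]
    contour(cbind(p$x_um, p$y_um))
  })
  out[unique(d$cell_id)]
}

#' Write cell contours to CSV
#'
#' @param contours named list of [contour()] objects.
#' @param path output CSV file path.
#' @export
write_contours_csv <- function(contours, path) {
  ids <- names(contours)
  if (is.null(ids)) ids <- sprintf("cell_%03d", seq_along(contours))
  rows <- lapply(seq_along(contours), function(i) {
    pts <- as_contour(contours[[i]])$points
    data.frame(cell_id = ids[i], vertex_index = seq_len(nrow(pts)),
               x_um = pts[, 1L], y_um = pts[, 2L])
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write a per-cell geometry table to TSV
#'
#' @param geometry data.frame from [quantify_cells()].
#' @param path output TSV file path.
#' @export
write_geometry_tsv <- function(geometry, path) {
  utils::write.table(geometry, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a per-cell geometry table from TSV
#'
#' @param path TSV file path.
#' @return data.frame.
#' @export
read_geometry_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write rendered cell channels to a multi-page 16-bit TIFF
#'
#' Channels (brightfield, marker, mask) are clamped to `[0, 1]` and
#' written as consecutive pages.
#'
#' @param rendered list with `brightfield`, `marker`, `mask` matrices
#'   (from [render_cell()] or [render_field()]).
#' @param path output TIFF path.
#' @export
write_cell_tiff <- function(rendered, path) {
  ch <- list(rendered$brightfield, rendered$marker, rendered$mask)
  ch <- lapply(ch, function(m) pmin(pmax(m, 0), 1))
  tiff::writeTIFF(ch, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page TIFF into a list of channel matrices
#'
#' @param path TIFF path.
#' @return list of numeric matrices named `brightfield`, `marker`,
#'   `mask` when three pages are present, else unnamed.
#' @export
read_cell_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) == 3L) names(pages) <- c("brightfield", "marker", "mask")
  pages
}

#' Read a study configuration (YAML or JSON)
#'
#' The file defines the generative size law and the culture panel:
#' top-level keys `size_law` (fields of [size_law_spec()]) and `cultures`
#' (list of [culture_spec()] fields).
#'
#' @param path YAML or JSON file.
#' @return list with `law` (a `"size_law_spec"`) and `panel` (list of
#'   `"culture_spec"`).
#' @export
read_study_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  law_args <- cfg$size_law
  if (!is.null(law_args$width_rules))
    law_args$width_rules <- lapply(law_args$width_rules, as.numeric)
  law <- do.call(size_law_spec, as.list(law_args))
  panel <- lapply(cfg$cultures, function(cu) do.call(culture_spec,
                                                     as.list(cu)))
  list(law = law, panel = panel)
}

#' Write size-law fits and a collapse test to JSON
#'
#' @param fits named list of `"size_law_fit"` objects.
#' @param collapse optional `"collapse_test"`.
#' @param path output JSON path.
#' @export
write_fits_json <- function(fits, collapse = NULL, path) {
  strip <- function(f) {
    f <- unclass(f)
    f$fit <- NULL
    f
  }
  out <- list(fits = lapply(fits, strip))
  if (!is.null(collapse)) {
    cl <- unclass(collapse)
    cl$shared_fit <- strip(cl$shared_fit)
    cl$separate_fits <- lapply(cl$separate_fits, strip)
    out$collapse <- cl
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
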