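#' Read an 8-bit RGB slide image (PNG or TIFF)
#'
#' The physical scale can come from TIFF resolution tags (honored when
#' present) or be supplied directly; an explicitly supplied `mpp`
#' always wins over tags. PNG files carry no scale, so `mpp` is
#' mandatory for them.
#'
#' @param path Image path (`.png`, `.tif`, `.tiff`).
#' @param mpp Microns per pixel; overrides any embedded resolution.
#' @return A [slide_image()].
#' @export
read_slide_image <- function(path, mpp = NULL) {
  if (!file.exists(path)) stop("image not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    px <- png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    px <- tiff::readTIFF(path, info = TRUE)
    if (is.null(mpp)) {
      xres <- attr(px, "x.resolution")
      unit <- attr(px, "resolution.unit")
      if (!is.null(xres) && !is.null(unit) && xres > 0) {
        per_um <- switch(unit, inch = xres / 25400, cm = xres / 10000, NULL)
        if (!is.null(per_um)) mpp <- 1 / per_um
      }
    }
  } else {
    stop("unsupported image format '", ext, "' (use PNG or TIFF)",
         call. = FALSE)
  }
  if (is.null(mpp)) {
    stop("microns-per-pixel unknown: supply `mpp` (--mpp on the command line)",
         call. = FALSE)
  }
  if (length(dim(px)) == 2L) px <- array(rep(px, 3), c(dim(px), 3L))
  if (dim(px)[3] > 3L) px <- px[, , 1:3, drop = FALSE]  # drop alpha
  slide_image(round(px * 255), mpp)
}

#' Write a slide image as PNG
#'
#' @param image A [slide_image()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_slide_image <- function(image, path) {
  stopifnot(inherits(image, "slide_image"))
  png::writePNG(image$pixels / 255, path)
  invisible(path)
}

#' Write nucleus detections to CSV
#'
#' Columns: `x_px`, `y_px`, `area_px2`, `mean_dab_od`, `mean_hema_od`,
#' `label`.
#'
#' @param detections Detection tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_detections_csv <- function(detections, path) {
  readr::write_csv(detections, path, na = "")
  invisible(path)
}

#' Write the per-tile table to CSV
#'
#' Undefined percentages (zero-cell tiles) are written as empty fields.
#'
#' @param tiles Counted tile tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tiles_csv <- function(tiles, path) {
  readr::write_csv(
    tiles[c("row", "col", "x0_px", "y0_px", "x1_px", "y1_px",
            "total_cells", "positive_cells", "percent_positive")],
    path, na = "")
  invisible(path)
}

#' Write a slide-score summary to JSON
#'
#' The summary embeds the resolved parameters so any run can be
#' reproduced from its own output.
#'
#' @param score A `slide_score`.
#' @param path Output path.
#' @param slide_id Identifier recorded in the summary.
#' @return `path`, invisibly.
#' @export
write_score_json <- function(score, path, slide_id = NA_character_) {
  stopifnot(inherits(score, "slide_score"))
  out <- c(list(slide_id = slide_id), as.list(score$summary),
           list(params = score$params))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a two-column CSV of paired scores
#'
#' Rows with a missing value in either column are dropped with a
#' message.
#'
#' @param path CSV with at least two numeric columns; the first two are
#'   used as (x, y).
#' @return Tibble with columns `x`, `y`.
#' @export
read_pairs_csv <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE)
  if (ncol(d) < 2L) stop("pairs file must have two columns", call. = FALSE)
  d <- tibble::tibble(x = as.numeric(d[[1]]), y = as.numeric(d[[2]]))
  keep <- stats::complete.cases(d)
  if (any(!keep)) {
    message(sprintf("dropped %d incomplete pair(s)", sum(!keep)))
  }
  d[keep, ]
}
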