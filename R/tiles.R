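#' Partition an annotated region into square tiles
#'
#' Lays a grid of `tile_size_um` x `tile_size_um` tiles over the
#' region, anchored at the top-left corner of the region's bounding
#' box. Tile boxes are half-open, `[x0, x1) x [y0, y1)`, so every
#' interior point belongs to exactly one tile; a tile is kept iff its
#' box intersects the region (partial edge tiles are kept — they
#' contain tumor — though they rarely accumulate enough cells to
#' qualify as hot spots).
#'
#' @param region A [region_annotation()].
#' @param mpp Microns per pixel.
#' @param tile_size_um Tile side in microns (500 by default, the
#'   standard tile used for whole-slide Ki67 scoring).
#' @return A tibble of empty tiles: `row`, `col`, `x0_px`, `y0_px`,
#'   `x1_px`, `y1_px`, `total_cells` (0), `positive_cells` (0),
#'   `percent_positive` (`NA`); grid origin and side length are
#'   attached as attributes.
#' @export
build_grid <- function(region, mpp, tile_size_um = 500) {
  stopifnot(inherits(region, "region_annotation"))
  if (tile_size_um <= 0 || mpp <= 0) {
    stop("`tile_size_um` and `mpp` must be positive", call. = FALSE)
  }
  if (region_area_px2(region) <= 0) {
    stop("annotated region has zero area", call. = FALSE)
  }
  side <- round(tile_size_um / mpp)
  if (side < 1) stop("tile size is below one pixel at this mpp", call. = FALSE)
  bb <- region_bbox(region)
  ncol_ <- max(1L, ceiling((bb["xmax"] - bb["xmin"]) / side))
  nrow_ <- max(1L, ceiling((bb["ymax"] - bb["ymin"]) / side))
  grid <- tidyr::expand_grid(row = seq_len(nrow_) - 1L,
                             col = seq_len(ncol_) - 1L)
  grid <- dplyr::mutate(grid,
    x0_px = bb[["xmin"]] + .data$col * side,
    y0_px = bb[["ymin"]] + .data$row * side,
    x1_px = .data$x0_px + side,
    y1_px = .data$y0_px + side
  )
  keep <- purrr::pmap_lgl(grid, function(row, col, x0_px, y0_px, x1_px, y1_px) {
    box_intersects_region(x0_px, y0_px, x1_px, y1_px, region)
  })
  tiles <- dplyr::mutate(grid[keep, , drop = FALSE],
                         total_cells = 0L,
                         positive_cells = 0L,
                         percent_positive = NA_real_)
  attr(tiles, "grid_origin") <- c(x = bb[["xmin"]], y = bb[["ymin"]])
  attr(tiles, "tile_side_px") <- side
  tiles
}

#' Count labeled nuclei per tile
#'
#' A detection contributes iff its centroid lies inside the region
#' polygon (boundary counts as inside) and inside a tile's half-open
#' box; each contributing detection is counted in exactly one tile.
#' Tiles left with zero cells keep an undefined (`NA`) percentage.
#'
#' @param detections Labeled tibble from [classify_detections()].
#' @param tiles Tile tibble from [build_grid()].
#' @param region The same [region_annotation()] used to build the grid.
#' @return `tiles` with `total_cells`, `positive_cells`,
#'   `percent_positive` filled.
#' @export
count_per_tile <- function(detections, tiles, region) {
  origin <- attr(tiles, "grid_origin")
  side <- attr(tiles, "tile_side_px")
  if (is.null(origin) || is.null(side)) {
    stop("`tiles` must come from build_grid()", call. = FALSE)
  }
  if (nrow(detections) > 0 && anyNA(detections$label)) {
    stop("detections must be classified before counting", call. = FALSE)
  }
  out <- dplyr::mutate(tiles, total_cells = 0L, positive_cells = 0L,
                       percent_positive = NA_real_)
  if (nrow(detections) > 0) {
    inside <- points_in_region(detections$x_px, detections$y_px, region)
    d <- detections[inside, , drop = FALSE]
    if (nrow(d) > 0) {
      counts <- d |>
        dplyr::mutate(col = floor((.data$x_px - origin[["x"]]) / side),
                      row = floor((.data$y_px - origin[["y"]]) / side)) |>
        dplyr::count(.data$row, .data$col,
                     wt = NULL, name = "n_total") |>
        dplyr::left_join(
          d |>
            dplyr::mutate(col = floor((.data$x_px - origin[["x"]]) / side),
                          row = floor((.data$y_px - origin[["y"]]) / side)) |>
            dplyr::filter(.data$label == "positive") |>
            dplyr::count(.data$row, .data$col, name = "n_pos"),
          by = c("row", "col")
        ) |>
        dplyr::mutate(n_pos = dplyr::coalesce(.data$n_pos, 0L))
      out <- out |>
        dplyr::left_join(counts, by = c("row", "col")) |>
        dplyr::mutate(
          total_cells = dplyr::coalesce(.data$n_total, 0L),
          positive_cells = dplyr::coalesce(.data$n_pos, 0L),
          percent_positive = dplyr::if_else(
            .data$total_cells > 0L,
            100 * .data$positive_cells / .data$total_cells,
            NA_real_),
          n_total = NULL, n_pos = NULL
        )
    }
  }
  attr(out, "grid_origin") <- origin
  attr(out, "tile_side_px") <- side
  out
}

#' Hot-spot Ki67 index
#'
#' Mean percent-positive of the top `k` tiles among those containing at
#' least `min_cells` cells (the hot spots emerge as the top-ranked
#' tiles; no region is hand-picked). Qualifying tiles are ranked by
#' `percent_positive` descending, ties broken by larger `total_cells`
#' and then by grid order, so repeated runs are byte-identical. When
#' fewer than `k` tiles qualify, all qualifying tiles are averaged;
#' when none qualify the index is undefined (`NA`) and flagged.
#'
#' @param tiles Counted tile tibble from [count_per_tile()].
#' @param min_cells Minimum cells for a tile to qualify (500).
#' @param k Number of top tiles averaged (5).
#' @return One-row tibble: `hot_spot_index`, `n_qualifying_tiles`,
#'   `n_hotspot_tiles_used`, `hotspot_undefined`.
#' @export
hot_spot_index <- function(tiles, min_cells = 500, k = 5) {
  if (k <= 0 || min_cells < 0) {
    stop("`k` must be positive and `min_cells` non-negative", call. = FALSE)
  }
  qual <- tiles |>
    dplyr::filter(.data$total_cells >= min_cells) |>
    dplyr::arrange(dplyr::desc(.data$percent_positive),
                   dplyr::desc(.data$total_cells), .data$row, .data$col)
  n_qual <- nrow(qual)
  if (n_qual == 0L) {
    warning("no tile reaches the minimum cell count; hot-spot index undefined",
            call. = FALSE)
    return(tibble::tibble(hot_spot_index = NA_real_,
                          n_qualifying_tiles = 0L,
                          n_hotspot_tiles_used = 0L,
                          hotspot_undefined = TRUE))
  }
  used <- min(k, n_qual)
  tibble::tibble(
    hot_spot_index = mean(qual$percent_positive[seq_len(used)]),
    n_qualifying_tiles = n_qual,
    n_hotspot_tiles_used = as.integer(used),
    hotspot_undefined = FALSE
  )
}

#' Whole-slide Ki67 index
#'
#' Unweighted (macro) mean of the per-tile percent-positive over all
#' tiles containing at least one cell; no minimum-cell criterion is
#' applied. Zero-cell tiles have an undefined percentage (0/0) and are
#' excluded rather than counted as 0%, which would deflate scores for
#' sparsely annotated regions.
#'
#' @param tiles Counted tile tibble from [count_per_tile()].
#' @return One-row tibble: `whole_slide_index`, `n_tiles_with_cells`.
#' @export
whole_slide_index <- function(tiles) {
  counted <- dplyr::filter(tiles, .data$total_cells >= 1L)
  tibble::tibble(
    whole_slide_index = if (nrow(counted) == 0L) NA_real_ else
      mean(counted$percent_positive),
    n_tiles_with_cells = nrow(counted)
  )
}

#' Score a slide end to end
#'
#' Composes the full pipeline: stain unmixing, nucleus detection and
#' classification, tiling of the annotated region, per-tile counting,
#' and both Ki67 indices. Deterministic for fixed inputs and
#' parameters.
#'
#' @param image A [slide_image()].
#' @param region A [region_annotation()] in the image's pixel space.
#' @param params A [detection_params()] bundle.
#' @param basis A [stain_basis()] matrix.
#' @param tile_size_um Tile side in microns.
#' @param min_cells Hot-spot qualification threshold.
#' @param k Number of hot-spot tiles averaged.
#' @return An object of class `slide_score`: list with `summary`
#'   (one-row tibble), `tiles`, `detections`, and the resolved
#'   parameters.
#' @export
score_slide <- function(image, region, params = detection_params(),
                        basis = stain_basis(), tile_size_um = 500,
                        min_cells = 500, k = 5) {
  stopifnot(inherits(image, "slide_image"))
  detections <- find_nuclei(image, params, basis)
  tiles <- build_grid(region, image$mpp, tile_size_um)
  tiles <- count_per_tile(detections, tiles, region)
  score_tiles(tiles, detections = detections, min_cells = min_cells, k = k,
              params = list(mpp = image$mpp, tile_size_um = tile_size_um,
                            min_cells = min_cells, k = k,
                            detection = unclass(params)))
}

# shared assembly of a slide_score from a counted tile table
score_tiles <- function(tiles, detections = NULL, min_cells = 500, k = 5,
                        params = list()) {
  hs <- hot_spot_index(tiles, min_cells, k)
  ws <- whole_slide_index(tiles)
  summary <- tibble::tibble(
    hot_spot_index = hs$hot_spot_index,
    whole_slide_index = ws$whole_slide_index,
    n_tiles = nrow(tiles),
    n_qualifying_tiles = hs$n_qualifying_tiles,
    n_hotspot_tiles_used = hs$n_hotspot_tiles_used,
    hotspot_undefined = hs$hotspot_undefined
  )
  structure(list(summary = summary, tiles = tiles,
                 detections = detections, params = params),
            class = "slide_score")
}

#' @export
print.slide_score <- function(x, ...) {
  s <- x$summary
  cat("<slide_score>\n")
  cat(sprintf("  hot-spot Ki67 index:    %s\n",
              if (is.na(s$hot_spot_index)) "undefined" else
                sprintf("%.2f%% (top %d of %d qualifying tiles)",
                        s$hot_spot_index, s$n_hotspot_tiles_used,
                        s$n_qualifying_tiles)))
  cat(sprintf("  whole-slide Ki67 index: %s\n",
              if (is.na(s$whole_slide_index)) "undefined" else
                sprintf("%.2f%%", s$whole_slide_index)))
  cat(sprintf("  tiles: %d\n", s$n_tiles))
  invisible(x)
}

#' @rdname tidy.slide_score
#' @method glance slide_score
#' @export
glance.slide_score <- function(x, ...) x$summary

#' Tidiers for slide scores
#'
#' `tidy()` returns the per-tile table; `glance()` the one-row summary
#' with both Ki67 indices.
#'
#' @param x A `slide_score`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy slide_score
#' @export
tidy.slide_score <- function(x, ...) x$tiles
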