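#' Tumor-region annotation
#'
#' One or more simple polygons, each optionally with holes, marking the
#' tumor-bearing area in pixel coordinates (0-based, y-down). Vertex
#' order does not matter; rings are closed implicitly.
#'
#' @param ... Polygons. Each is either an `n x 2` matrix (outer ring
#'   only) or a list with elements `outer` (`n x 2` matrix) and
#'   optionally `holes` (list of `n x 2` matrices).
#' @return An object of class `region_annotation`.
#' @export
region_annotation <- function(...) {
  polys <- lapply(list(...), function(p) {
    if (is.matrix(p)) p <- list(outer = p, holes = list())
    if (is.null(p$holes)) p$holes <- list()
    stopifnot(is.matrix(p$outer), ncol(p$outer) == 2L)
    if (nrow(p$outer) < 3L || abs(ring_area(p$outer)) <= 0) {
      stop("each polygon must have at least 3 vertices and area > 0",
           call. = FALSE)
    }
    p
  })
  if (length(polys) == 0L) {
    stop("annotation must contain at least one polygon", call. = FALSE)
  }
  structure(polys, class = "region_annotation")
}

# signed area of a ring (shoelace); sign encodes orientation
ring_area <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  j <- c(nrow(ring), seq_len(nrow(ring) - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

#' Region area in square pixels
#' @param region A [region_annotation()].
#' @return Total area (outer rings minus holes), px^2.
#' @export
region_area_px2 <- function(region) {
  sum(vapply(region, function(p) {
    abs(ring_area(p$outer)) -
      sum(vapply(p$holes, function(h) abs(ring_area(h)), numeric(1)))
  }, numeric(1)))
}

# Points-in-ring test, vectorized over points. Crossing-number with an
# explicit on-boundary check; `boundary` decides what on-edge returns.
points_in_ring <- function(x, y, ring, boundary = TRUE, eps = 1e-9) {
  n <- nrow(ring)
  rx <- ring[, 1]; ry <- ring[, 2]
  jx <- rx[c(n, seq_len(n - 1L))]; jy <- ry[c(n, seq_len(n - 1L))]
  inside <- rep(FALSE, length(x))
  on_edge <- rep(FALSE, length(x))
  for (k in seq_len(n)) {
    x1 <- jx[k]; y1 <- jy[k]; x2 <- rx[k]; y2 <- ry[k]
    # on-segment check
    dx <- x2 - x1; dy <- y2 - y1
    len2 <- dx * dx + dy * dy
    if (len2 > 0) {
      t <- ((x - x1) * dx + (y - y1) * dy) / len2
      t <- pmin(pmax(t, 0), 1)
      d2 <- (x - (x1 + t * dx))^2 + (y - (y1 + t * dy))^2
      on_edge <- on_edge | d2 <= eps^2
    } else {
      on_edge <- on_edge | ((x - x1)^2 + (y - y1)^2 <= eps^2)
    }
    # crossing test (half-open in y to count each vertex once)
    crosses <- ((y1 > y) != (y2 > y)) &
      (x < x1 + (y - y1) * (x2 - x1) / (y2 - y1))
    crosses[is.na(crosses)] <- FALSE
    inside <- xor(inside, crosses)
  }
  ifelse(on_edge, boundary, inside)
}

#' Which points fall inside the annotated region
#'
#' A point is inside when it lies in some polygon's outer ring (ring
#' boundary counts as inside) and not strictly inside any of that
#' polygon's holes (a point on a hole's boundary still counts as
#' inside the region). This single rule is used everywhere a centroid
#' is assigned to the region.
#'
#' @param x,y Numeric vectors of pixel coordinates.
#' @param region A [region_annotation()].
#' @return Logical vector.
#' @export
points_in_region <- function(x, y, region) {
  stopifnot(inherits(region, "region_annotation"), length(x) == length(y))
  res <- rep(FALSE, length(x))
  for (p in region) {
    in_outer <- points_in_ring(x, y, p$outer, boundary = TRUE)
    in_hole <- rep(FALSE, length(x))
    for (h in p$holes) {
      in_hole <- in_hole | points_in_ring(x, y, h, boundary = FALSE)
    }
    res <- res | (in_outer & !in_hole)
  }
  res
}

# do segments (p1,p2) and (p3,p4) intersect (including touching)?
segments_intersect <- function(p1, p2, p3, p4) {
  orient <- function(a, b, c) {
    v <- (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
    sign(v)
  }
  on_seg <- function(a, b, c) {
    min(a[1], b[1]) <= c[1] && c[1] <= max(a[1], b[1]) &&
      min(a[2], b[2]) <= c[2] && c[2] <= max(a[2], b[2])
  }
  o1 <- orient(p1, p2, p3); o2 <- orient(p1, p2, p4)
  o3 <- orient(p3, p4, p1); o4 <- orient(p3, p4, p2)
  if (o1 != o2 && o3 != o4) return(TRUE)
  (o1 == 0 && on_seg(p1, p2, p3)) || (o2 == 0 && on_seg(p1, p2, p4)) ||
    (o3 == 0 && on_seg(p3, p4, p1)) || (o4 == 0 && on_seg(p3, p4, p2))
}

# Does the closed axis-aligned box [x0,x1]x[y0,y1] intersect the region?
box_intersects_region <- function(x0, y0, x1, y1, region) {
  corners_x <- c(x0, x1, x1, x0)
  corners_y <- c(y0, y0, y1, y1)
  box_ring <- cbind(corners_x, corners_y)
  for (p in region) {
    ring <- p$outer
    # any outer vertex inside the box
    if (any(ring[, 1] >= x0 & ring[, 1] <= x1 &
            ring[, 2] >= y0 & ring[, 2] <= y1)) {
      hit <- TRUE
    } else if (any(points_in_ring(corners_x, corners_y, ring,
                                  boundary = TRUE))) {
      # box corner inside the polygon
      hit <- TRUE
    } else {
      # edge crossings
      hit <- FALSE
      n <- nrow(ring)
      for (i in seq_len(n)) {
        a <- ring[i, ]; b <- ring[if (i == n) 1L else i + 1L, ]
        for (j in 1:4) {
          c1 <- box_ring[j, ]; c2 <- box_ring[if (j == 4L) 1L else j + 1L, ]
          if (segments_intersect(a, b, c1, c2)) { hit <- TRUE; break }
        }
        if (hit) break
      }
    }
    if (!hit) next
    # discard if the whole box sits strictly inside a hole
    in_hole <- FALSE
    for (h in p$holes) {
      if (all(points_in_ring(corners_x, corners_y, h, boundary = FALSE))) {
        crossed <- FALSE
        n <- nrow(h)
        for (i in seq_len(n)) {
          a <- h[i, ]; b <- h[if (i == n) 1L else i + 1L, ]
          for (j in 1:4) {
            c1 <- box_ring[j, ]; c2 <- box_ring[if (j == 4L) 1L else j + 1L, ]
            if (segments_intersect(a, b, c1, c2)) { crossed <- TRUE; break }
          }
          if (crossed) break
        }
        if (!crossed) { in_hole <- TRUE; break }
      }
    }
    if (!in_hole) return(TRUE)
  }
  FALSE
}

# bounding box over all outer rings
region_bbox <- function(region) {
  xs <- unlist(lapply(region, function(p) p$outer[, 1]))
  ys <- unlist(lapply(region, function(p) p$outer[, 2]))
  c(xmin = min(xs), ymin = min(ys), xmax = max(xs), ymax = max(ys))
}

#' Read a region annotation from GeoJSON
#'
#' Accepts a FeatureCollection (or bare geometry) of Polygon /
#' MultiPolygon features with coordinates already in pixel units
#' (0-based, y-down). Any CRS member is ignored; the first ring of each
#' polygon is the outer ring, subsequent rings are holes.
#'
#' @param path Path to a GeoJSON file.
#' @return A [region_annotation()].
#' @export
read_region_geojson <- function(path) {
  gj <- tryCatch(
    jsonlite::read_json(path, simplifyVector = FALSE),
    error = function(e) {
      stop(sprintf("cannot parse GeoJSON '%s': %s", path, conditionMessage(e)),
           call. = FALSE)
    }
  )
  geoms <- list()
  if (identical(gj$type, "FeatureCollection")) {
    geoms <- lapply(gj$features, function(f) f$geometry)
  } else if (identical(gj$type, "Feature")) {
    geoms <- list(gj$geometry)
  } else if (gj$type %in% c("Polygon", "MultiPolygon")) {
    geoms <- list(gj)
  } else {
    stop(sprintf("unsupported GeoJSON type '%s' in %s", gj$type, path),
         call. = FALSE)
  }
  ring_to_matrix <- function(r) {
    m <- do.call(rbind, lapply(r, function(pt) c(pt[[1]], pt[[2]])))
    # drop the closing duplicate vertex if present
    if (nrow(m) > 1L && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
    m
  }
  polys <- list()
  for (g in geoms) {
    if (is.null(g)) next
    coord_sets <- switch(g$type,
      Polygon = list(g$coordinates),
      MultiPolygon = g$coordinates,
      stop(sprintf("unsupported geometry type '%s'", g$type), call. = FALSE)
    )
    for (cs in coord_sets) {
      rings <- lapply(cs, ring_to_matrix)
      polys <- c(polys, list(list(outer = rings[[1]],
                                  holes = rings[-1])))
    }
  }
  do.call(region_annotation, polys)
}

#' Write a region annotation to GeoJSON
#'
#' @param region A [region_annotation()].
#' @param path Output path.
#' @param name Optional feature name property.
#' @return `path`, invisibly.
#' @export
write_region_geojson <- function(region, path, name = NULL) {
  close_ring <- function(m) {
    m <- rbind(m, m[1, ])
    lapply(seq_len(nrow(m)), function(i) c(m[i, 1], m[i, 2]))
  }
  feats <- lapply(region, function(p) {
    coords <- c(list(close_ring(p$outer)), lapply(p$holes, close_ring))
    props <- if (is.null(name)) stats::setNames(list(), character()) else
      list(name = name)
    list(type = "Feature",
         properties = props,
         geometry = list(type = "Polygon", coordinates = coords))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Rectangular annotation helper
#'
#' @param x0,y0,x1,y1 Corners in pixel coordinates.
#' @return A [region_annotation()] covering the rectangle.
#' @export
rect_region <- function(x0, y0, x1, y1) {
  region_annotation(cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1)))
}
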