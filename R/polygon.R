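#' Planar polygon (one or more rings)
#'
#' Lightweight polygon container used for study areas and range constraints.
#' Each ring is an n x 2 coordinate matrix (not necessarily closed); a point
#' is inside the polygon if it is inside (or on the boundary of) any ring.
#' Holes are not supported.
#'
#' @param rings a single n x 2 matrix or a list of them.
#' @return an object of class `area_polygon`.
#' @export
area_polygon <- function(rings) {
  if (is.matrix(rings)) rings <- list(rings)
  rings <- lapply(rings, function(r) {
    r <- as.matrix(r)
    if (ncol(r) != 2 || nrow(r) < 3) stop_ns("each ring needs >= 3 x,y points")
    storage.mode(r) <- "double"
    # drop a duplicated closing vertex; containment tests do not need it
    if (all(r[1, ] == r[nrow(r), ])) r <- r[-nrow(r), , drop = FALSE]
    r
  })
  structure(list(rings = rings), class = "area_polygon")
}

#' @export
print.area_polygon <- function(x, ...) {
  cat("<area_polygon> ", length(x$rings), " ring(s), total area ",
      format(polygon_area(x), digits = 6), "\n", sep = "")
  invisible(x)
}

#' Point-in-polygon test (boundary counts as inside)
#'
#' @param poly an [area_polygon()].
#' @param x,y coordinate vectors.
#' @return logical vector.
#' @export
polygon_contains <- function(poly, x, y) {
  inside <- rep(FALSE, length(x))
  for (r in poly$rings) {
    res <- pracma::inpolygon(x, y, r[, 1], r[, 2], boundary = TRUE)
    inside <- inside | res
  }
  inside
}

#' Total polygon area (shoelace formula, rings summed)
#'
#' @param poly an [area_polygon()].
#' @return area in squared planar units.
#' @export
polygon_area <- function(poly) {
  sum(vapply(poly$rings, function(r) {
    x <- r[, 1]; y <- r[, 2]
    j <- c(seq_len(nrow(r))[-1], 1L)
    abs(sum(x * y[j] - x[j] * y)) / 2
  }, numeric(1)))
}

#' Rectangle helper
#'
#' @param xmin,xmax,ymin,ymax rectangle bounds.
#' @return an [area_polygon()].
#' @export
rectangle_polygon <- function(xmin, xmax, ymin, ymax) {
  area_polygon(cbind(c(xmin, xmax, xmax, xmin),
                     c(ymin, ymin, ymax, ymax)))
}

#' Minimum convex polygon with buffer
#'
#' Convex hull of the occurrence coordinates dilated by `buffer_km` in the
#' planar frame (the standard accessible-area constraint for niche-model
#' projection). Degenerate inputs fall back gracefully: a single point gives a
#' disk, collinear points a capsule. Arcs are approximated with 5-degree steps,
#' keeping disk areas within ~0.1% of the closed form.
#'
#' @param occ an [occurrence_set()] (or an n x 2 coordinate matrix).
#' @param buffer_km dilation distance (>= 0), default 25.
#' @return an [area_polygon()].
#' @export
mcp_buffer <- function(occ, buffer_km = 25) {
  pts <- if (inherits(occ, "occurrence_set")) {
    cbind(occ$lon, occ$lat)
  } else {
    as.matrix(occ)
  }
  pts <- unique(pts[stats::complete.cases(pts), , drop = FALSE])
  if (nrow(pts) == 0L) stop_ns("no coordinates to buffer")
  if (buffer_km < 0) stop_ns("buffer_km must be >= 0")
  hull_idx <- grDevices::chull(pts[, 1], pts[, 2])
  hull <- pts[hull_idx, , drop = FALSE]
  step <- pi / 36  # 5 degrees
  if (nrow(hull) == 1L || buffer_km > 0 && all(dist(hull) < 1e-12)) {
    if (buffer_km == 0) return(area_polygon(rbind(hull, hull, hull) +
                                              c(0, 1e-12, -1e-12)))
    ang <- seq(0, 2 * pi, by = step)
    return(area_polygon(cbind(hull[1, 1] + buffer_km * cos(ang),
                              hull[1, 2] + buffer_km * sin(ang))))
  }
  if (nrow(hull) == 2L) {
    # collinear points: capsule around the extreme segment
    a <- hull[1, ]; b <- hull[2, ]
    if (buffer_km == 0) {
      eps <- 1e-9 * max(1, sqrt(sum((b - a)^2)))
      n <- (b - a) / sqrt(sum((b - a)^2)); n <- c(-n[2], n[1]) * eps
      return(area_polygon(rbind(a + n, b + n, b - n, a - n)))
    }
    u <- (b - a) / sqrt(sum((b - a)^2))
    th0 <- atan2(u[2], u[1])
    arc1 <- th0 + pi / 2 + seq(0, pi, by = step)   # around a
    arc2 <- th0 - pi / 2 + seq(0, pi, by = step)   # around b
    ring <- rbind(
      cbind(a[1] + buffer_km * cos(arc1), a[2] + buffer_km * sin(arc1)),
      cbind(b[1] + buffer_km * cos(arc2), b[2] + buffer_km * sin(arc2))
    )
    return(area_polygon(ring))
  }
  # hull vertices in counter-clockwise order for outward normals
  hull <- hull[rev(seq_len(nrow(hull))), , drop = FALSE]  # chull is clockwise
  if (signed_area(hull) < 0) hull <- hull[rev(seq_len(nrow(hull))), , drop = FALSE]
  if (buffer_km == 0) return(area_polygon(hull))
  n <- nrow(hull)
  ring <- NULL
  for (i in seq_len(n)) {
    p_prev <- hull[if (i == 1) n else i - 1, ]
    p <- hull[i, ]
    p_next <- hull[if (i == n) 1 else i + 1, ]
    e_in <- p - p_prev
    e_out <- p_next - p
    # outward normal angles of incoming and outgoing edges (CCW polygon)
    a_in <- atan2(e_in[2], e_in[1]) - pi / 2
    a_out <- atan2(e_out[2], e_out[1]) - pi / 2
    sweep <- (a_out - a_in) %% (2 * pi)
    ang <- a_in + seq(0, sweep, by = step)
    if (ang[length(ang)] != a_in + sweep) ang <- c(ang, a_in + sweep)
    ring <- rbind(ring, cbind(p[1] + buffer_km * cos(ang),
                              p[2] + buffer_km * sin(ang)))
  }
  area_polygon(ring)
}

signed_area <- function(r) {
  x <- r[, 1]; y <- r[, 2]
  j <- c(seq_len(nrow(r))[-1], 1L)
  sum(x * y[j] - x[j] * y) / 2
}

#' Read / write simple GeoJSON polygons
#'
#' Supports `Polygon` and `MultiPolygon` geometries (outer rings only; holes
#' are ignored with a warning), either bare or wrapped in a Feature /
#' FeatureCollection.
#'
#' @param path file path.
#' @param poly an [area_polygon()].
#' @return `read_geojson_polygon` returns an [area_polygon()].
#' @export
read_geojson_polygon <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = FALSE)
  geom <- g
  if (identical(g$type, "FeatureCollection")) geom <- g$features[[1]]$geometry
  if (identical(geom$type, "Feature")) geom <- geom$geometry
  ring_mat <- function(ring) {
    do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
  }
  rings <- switch(
    geom$type,
    Polygon = {
      if (length(geom$coordinates) > 1L) {
        warning("polygon holes are ignored", call. = FALSE)
      }
      list(ring_mat(geom$coordinates[[1]]))
    },
    MultiPolygon = lapply(geom$coordinates, function(pp) {
      if (length(pp) > 1L) warning("polygon holes are ignored", call. = FALSE)
      ring_mat(pp[[1]])
    }),
    stop_ns("unsupported GeoJSON geometry type: ", geom$type)
  )
  area_polygon(rings)
}

#' @rdname read_geojson_polygon
#' @export
write_geojson_polygon <- function(poly, path) {
  close_ring <- function(r) rbind(r, r[1, , drop = FALSE])
  coords <- lapply(poly$rings, function(r) list(unname(
    lapply(seq_len(nrow(r) + 1), function(i) {
      rc <- close_ring(r)
      c(rc[i, 1], rc[i, 2])
    })
  )))
  geom <- if (length(coords) == 1L) {
    list(type = "Polygon", coordinates = coords[[1]])
  } else {
    list(type = "MultiPolygon", coordinates = coords)
  }
  jsonlite::write_json(geom, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
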