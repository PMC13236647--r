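# Nearest-centroid (Voronoi) community polygons, built by clipping the
# extent rectangle with perpendicular-bisector half-planes. Only
# centroids close enough to cut the current cell are visited, so the
# construction stays fast for hundreds of communities.

# Clip a convex polygon (k x 2 matrix, open ring) by the half-plane
# {p : a . p <= b} (Sutherland-Hodgman).
clip_halfplane <- function(poly, a, b) {
  k <- nrow(poly)
  if (k == 0) return(poly)
  s <- poly %*% a - b
  inside <- s <= 1e-9
  out <- matrix(numeric(0), 0, 2)
  for (i in seq_len(k)) {
    j <- if (i == k) 1L else i + 1L
    if (inside[i]) out <- rbind(out, poly[i, ])
    if (xor(inside[i], inside[j])) {
      t <- s[i] / (s[i] - s[j])
      out <- rbind(out, poly[i, ] + t * (poly[j, ] - poly[i, ]))
    }
  }
  out
}

# Voronoi cell of point i within the extent rectangle.
voronoi_cell <- function(i, pts, extent) {
  poly <- rbind(
    c(0, 0), c(extent[1], 0), c(extent[1], extent[2]), c(0, extent[2])
  )
  ci <- pts[i, ]
  d <- sqrt((pts[, 1] - ci[1])^2 + (pts[, 2] - ci[2])^2)
  ord <- order(d)
  for (j in ord) {
    if (j == i) next
    # Max distance from ci to a current vertex; a bisector farther than
    # that cannot cut the cell, and distances only grow from here on.
    rmax <- sqrt(max((poly[, 1] - ci[1])^2 + (poly[, 2] - ci[2])^2))
    if (d[j] / 2 > rmax) break
    dir <- pts[j, ] - ci
    mid <- (pts[j, ] + ci) / 2
    poly <- clip_halfplane(poly, dir, sum(dir * mid))
    if (nrow(poly) < 3) break
  }
  poly
}

voronoi_polygons <- function(pts, extent) {
  lapply(seq_len(nrow(pts)), voronoi_cell, pts = pts, extent = extent)
}

# Shoelace area of an open polygon ring.
polygon_area <- function(poly) {
  if (nrow(poly) < 3) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(2:nrow(poly), 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Write communities to GeoJSON
#'
#' Emits a FeatureCollection of community polygons in planar meter
#' coordinates with id, region, and population properties, plus any extra
#' per-community columns supplied via `properties`.
#'
#' @param city A [generate_city()] result.
#' @param path Output file path.
#' @param properties Optional data frame keyed by `community_id` (or
#'   `id`) whose remaining columns become feature properties.
#' @param digits Coordinate digits written.
#' @return `path`, invisibly.
#' @export
write_communities_geojson <- function(city, path, properties = NULL, digits = 2) {
  com <- city$communities
  extra <- NULL
  if (!is.null(properties)) {
    key <- if ("community_id" %in% names(properties)) "community_id" else "id"
    extra <- properties[match(com$id, properties[[key]]), , drop = FALSE]
    extra <- extra[, setdiff(names(extra), key), drop = FALSE]
  }
  features <- lapply(seq_len(nrow(com)), function(i) {
    poly <- com$polygon[[i]]
    ring <- rbind(poly, poly[1, , drop = FALSE])
    props <- list(
      id = com$id[i], region = com$region[i], population = com$population[i],
      x = round(com$x[i], digits), y = round(com$y[i], digits)
    )
    if (!is.null(extra)) props <- c(props, as.list(extra[i, , drop = FALSE]))
    list(
      type = "Feature",
      properties = props,
      geometry = list(
        type = "Polygon",
        coordinates = list(lapply(seq_len(nrow(ring)), function(r) {
          round(as.numeric(ring[r, ]), digits)
        }))
      )
    )
  })
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
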