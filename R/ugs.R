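# Green-space quantity and quality covariates: NDVI from two-band
# reflectance, two-level street-view score aggregation, walking-catchment
# destination counts, and lockdown intensity.

#' Normalized difference vegetation index
#'
#' Computes the cellwise NDVI raster `(NIR - Red) / (NIR + Red)` from two
#' aligned surface-reflectance bands. Cells where `NIR + Red = 0` carry
#' no signal and are set to the nodata code. If `communities` is
#' supplied, per-community means over the footprint cells (nearest
#' centroid, nodata excluded) are returned alongside.
#'
#' @param nir,red Aligned [gm_raster()]s of reflectance in \[0, 1\].
#' @param communities Optional data frame with `id`, `x`, `y`.
#' @return A [gm_raster()] of NDVI in \[-1, 1\], or, with `communities`,
#'   a list with `raster` and `by_community` (tibble `community_id`,
#'   `ndvi`).
#' @export
#' @examples
#' nir <- gm_raster(matrix(0.6, 2, 2), cell_size = 10)
#' red <- gm_raster(matrix(0.2, 2, 2), cell_size = 10)
#' ndvi(nir, red)$values
ndvi <- function(nir, red, communities = NULL) {
  stopifnot(inherits(nir, "gm_raster"), inherits(red, "gm_raster"))
  if (!identical(dim(nir$values), dim(red$values)) ||
      !identical(nir$origin, red$origin) ||
      !identical(nir$cell_size, red$cell_size)) {
    abort("NIR and red rasters must share shape, origin and cell size.")
  }
  s <- nir$values + red$values
  v <- (nir$values - red$values) / s
  v[s == 0] <- -9999
  out <- gm_raster(v, origin = nir$origin, cell_size = nir$cell_size, nodata = -9999)
  if (is.null(communities)) return(out)
  cells <- raster_cells(out)
  keep <- cells$value != out$nodata
  assign <- nearest_index(
    cbind(cells$x, cells$y), cbind(communities$x, communities$y)
  )
  means <- vapply(seq_len(nrow(communities)), function(i) {
    vi <- cells$value[keep & assign == i]
    if (length(vi) == 0) NA_real_ else mean(vi)
  }, numeric(1))
  list(
    raster = out,
    by_community = tibble(community_id = communities$id, ndvi = means)
  )
}

#' Aggregate street-view point scores to communities
#'
#' Two-level mean mirroring how eye-level indicators are built from
#' multi-directional street images: first the mean over the available
#' viewing-direction scores at each sampling point, then the mean of
#' those point values over all points in a community. This is *not* the
#' pooled mean over all directions, which would overweight points with
#' more directions.
#'
#' @param scores Data frame with `point_id`, `community_id`, `kind`, and
#'   direction columns `d1`..`d4` (missing directions as `NA`).
#' @param kind Score kind to aggregate: `"gvi"`, `"openness"`, or
#'   `"walkability"`.
#' @param communities Optional vector of community ids that must appear
#'   in the output; communities without points get `NA` and a warning.
#' @return A tibble `community_id`, `value`.
#' @export
aggregate_streetview <- function(scores, kind = c("gvi", "openness", "walkability"),
                                 communities = NULL) {
  kind <- match.arg(kind)
  stopifnot(all(c("point_id", "community_id", "kind") %in% names(scores)))
  dcols <- intersect(paste0("d", 1:4), names(scores))
  if (length(dcols) == 0) abort("No direction columns d1..d4 found.")
  sc <- scores[scores$kind == kind, , drop = FALSE]
  pt <- sc |>
    mutate(point_value = rowMeans(across(dplyr::all_of(dcols)), na.rm = TRUE)) |>
    filter(is.finite(.data$point_value))
  out <- pt |>
    group_by(.data$community_id) |>
    summarise(value = mean(.data$point_value), .groups = "drop")
  if (!is.null(communities)) {
    out <- tibble(community_id = communities) |>
      left_join(out, by = "community_id")
    if (anyNA(out$value)) {
      warn(sprintf(
        "%d community(ies) have no %s sampling points; value set to NA.",
        sum(is.na(out$value)), kind
      ))
    }
  }
  out
}

#' Count reachable destinations within a walking catchment
#'
#' Counts candidate destinations whose network walking distance is within
#' the catchment threshold (closed boundary: a destination exactly at the
#' threshold counts).
#'
#' @param distances Numeric vector of network distances in meters (>= 0).
#' @param threshold Catchment radius in meters (default 1000, the 1 km
#'   daily-walking scale).
#' @return An integer count.
#' @export
#' @examples
#' catchment_count(c(400, 950, 1000, 1200)) # 3
catchment_count <- function(distances, threshold = 1000) {
  if (length(distances) == 0) return(0L)
  if (any(!is.finite(distances)) || any(distances < 0)) {
    abort("Distances must be finite and non-negative.")
  }
  if (threshold < 0) abort("`threshold` must be >= 0.")
  sum(distances <= threshold)
}

#' Lockdown intensity
#'
#' Fraction of the study window a community spent under mobility
#' restrictions: `locked_days / window_days`.
#'
#' @param locked_days Days under lockdown within the window (0 <=
#'   `locked_days` <= `window_days`).
#' @param window_days Total days in the window (> 0).
#' @return A fraction in \[0, 1\]; vectorized over communities.
#' @export
#' @examples
#' lockdown_intensity(30, 90)
lockdown_intensity <- function(locked_days, window_days) {
  if (any(window_days <= 0)) abort("`window_days` must be positive.")
  if (any(locked_days < 0) || any(locked_days > window_days)) {
    abort("`locked_days` must lie in [0, window_days].")
  }
  locked_days / window_days
}
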