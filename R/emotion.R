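# Community negative-emotion indicator: seasonal filtering of labeled
# geotagged posts, kernel density estimation of the negative-post point
# pattern, and population standardization.

#' Assign a meteorological season to timestamps
#'
#' March-May is spring, June-August summer, September-November autumn,
#' and December-February winter. Boundary days belong to the season they
#' open (e.g. March 1 is spring).
#'
#' @param timestamp A `Date`/`POSIXt` vector, or strings parsable by
#'   [as.POSIXct()].
#' @return A character vector of season ids.
#' @export
#' @examples
#' assign_season(as.Date(c("2022-04-15", "2022-12-25")))
assign_season <- function(timestamp) {
  if (is.character(timestamp)) {
    parsed <- tryCatch(
      as.POSIXct(timestamp, tz = "UTC"),
      error = function(e) abort("Timestamps could not be parsed.")
    )
    if (anyNA(parsed) && !anyNA(timestamp)) {
      abort("Some timestamps could not be parsed.")
    }
    timestamp <- parsed
  }
  if (!inherits(timestamp, c("Date", "POSIXt"))) {
    abort("`timestamp` must be Date, POSIXt, or parsable character.")
  }
  mo <- as.integer(format(timestamp, "%m"))
  out <- rep(NA_character_, length(mo))
  out[mo %in% 3:5] <- "spring"
  out[mo %in% 6:8] <- "summer"
  out[mo %in% 9:11] <- "autumn"
  out[mo %in% c(12, 1, 2)] <- "winter"
  out
}

#' Filter posts to one season's negative events
#'
#' Keeps posts labeled `negative` whose timestamp falls in `season`, and
#' returns their coordinates — the event set that feeds [kde_surface()].
#'
#' @param posts Data frame with `x`, `y`, `timestamp`, `sentiment`.
#' @param season A season id.
#' @return A tibble with columns `x`, `y`.
#' @export
negative_events <- function(posts, season) {
  check_season(season)
  stopifnot(all(c("x", "y", "timestamp", "sentiment") %in% names(posts)))
  keep <- posts$sentiment == "negative" & assign_season(posts$timestamp) == season
  as_tibble(posts[keep, c("x", "y"), drop = FALSE])
}

#' Define a regular analysis grid
#'
#' @param extent Width and height in meters (grid origin at (0, 0)), or
#'   pass `origin` for a shifted grid.
#' @param cell_size Cell size in meters.
#' @param origin Lower-left corner.
#' @return A `grid_spec` list (origin, cell_size, nx, ny).
#' @export
grid_spec <- function(extent, cell_size, origin = c(0, 0)) {
  check_number(cell_size, "cell_size", positive = TRUE)
  nx <- max(1L, ceiling(extent[1] / cell_size))
  ny <- max(1L, ceiling(extent[2] / cell_size))
  structure(
    list(origin = as.numeric(origin), cell_size = cell_size,
         nx = as.integer(nx), ny = as.integer(ny)),
    class = "grid_spec"
  )
}

# Supported kernels, parameterized on u = d/h with d the planar distance.
# Each integrates to 1 over the plane, so the surface
# sum_i K(u)/(n h^2) integrates to 1 when all kernels lie inside the grid.
kernel_value <- function(u2, kernel) {
  switch(kernel,
    quartic = ifelse(u2 <= 1, (3 / pi) * (1 - u2)^2, 0),
    gaussian = exp(-u2 / 2) / (2 * pi),
    uniform = ifelse(u2 <= 1, 1 / pi, 0),
    abort(sprintf("Unknown kernel '%s'.", kernel))
  )
}

# Effective support radius (in bandwidth units) used to window the
# accumulation; the Gaussian tail beyond 6 h is negligible.
kernel_support <- function(kernel) {
  switch(kernel, quartic = 1, uniform = 1, gaussian = 6)
}

#' Kernel density surface of point events
#'
#' Evaluates the fixed-bandwidth planar kernel density estimate
#' `f(s) = sum_i K((s - s_i)/h) / (n h^2)` at every grid-cell center.
#' The default quartic (biweight) kernel `K(u) = (3/pi)(1 - |u|^2)^2` on
#' the unit disk matches the kernel used by desktop GIS density tools;
#' Gaussian and uniform kernels are also available. With any of these,
#' the surface integrates to ~1 whenever all kernel supports lie inside
#' the grid.
#'
#' @param events Data frame or matrix of event coordinates `x`, `y`.
#' @param grid A [grid_spec()].
#' @param bandwidth Kernel bandwidth h in meters (> 0).
#' @param kernel `"quartic"` (default), `"gaussian"`, or `"uniform"`.
#' @return A `density_surface` (a [gm_raster()] subclass) with fields
#'   `bandwidth`, `kernel`, `n_events`.
#' @export
#' @examples
#' g <- grid_spec(c(10, 10), 0.5)
#' s <- kde_surface(data.frame(x = 5, y = 5), g, bandwidth = 2)
#' sum(s$values) * 0.5^2 # ~1
kde_surface <- function(events, grid, bandwidth, kernel = "quartic") {
  events <- as.matrix(as.data.frame(events)[, c("x", "y")])
  if (nrow(events) == 0) abort("`events` is empty; KDE needs at least one event.")
  if (any(!is.finite(events))) abort("Event coordinates must be finite.")
  check_number(bandwidth, "bandwidth", positive = TRUE)
  stopifnot(inherits(grid, "grid_spec"))
  kernel <- match.arg(kernel, c("quartic", "gaussian", "uniform"))

  n <- nrow(events)
  h <- bandwidth
  cs <- grid$cell_size
  nx <- grid$nx
  ny <- grid$ny
  x0 <- grid$origin[1]
  y0 <- grid$origin[2]
  xs <- x0 + (seq_len(nx) - 0.5) * cs
  ys_bottom <- y0 + (seq_len(ny) - 0.5) * cs # index 1 = southernmost

  vals <- matrix(0, nrow = ny, ncol = nx) # row 1 = south, flipped at the end
  support <- kernel_support(kernel) * h
  norm <- 1 / (n * h^2)
  for (e in seq_len(n)) {
    ex <- events[e, 1]; ey <- events[e, 2]
    jr <- range(ceiling((ex - support - x0) / cs), floor((ex + support - x0) / cs) + 1L)
    ir <- range(ceiling((ey - support - y0) / cs), floor((ey + support - y0) / cs) + 1L)
    j1 <- max(1L, jr[1]); j2 <- min(nx, jr[2])
    i1 <- max(1L, ir[1]); i2 <- min(ny, ir[2])
    if (j1 > j2 || i1 > i2) next
    dx2 <- (xs[j1:j2] - ex)^2
    dy2 <- (ys_bottom[i1:i2] - ey)^2
    u2 <- outer(dy2, dx2, "+") / h^2
    vals[i1:i2, j1:j2] <- vals[i1:i2, j1:j2] + norm * kernel_value(u2, kernel)
  }
  r <- gm_raster(vals[ny:1, , drop = FALSE], origin = c(x0, y0), cell_size = cs)
  r$bandwidth <- h
  r$kernel <- kernel
  r$n_events <- n
  class(r) <- c("density_surface", class(r))
  r
}

#' Population-standardized community emotion indicator
#'
#' Averages the density surface over each community footprint (the cells
#' whose centers are nearest to the community's centroid) and divides by
#' the community's population in units of 10,000 residents, so the index
#' reads as negative-post density per 10,000 residents.
#'
#' @param surface A [kde_surface()] result.
#' @param communities Data frame with `id`, `x`, `y` (community
#'   centroids; footprints are their nearest-centroid cells).
#' @param populations Numeric vector of resident counts aligned with
#'   `communities`, or a column name in `communities` (default
#'   `"population"`).
#' @param season Optional season id recorded in the output.
#' @return A tibble: `community_id`, `season`, `raw_density`,
#'   `population`, `index`.
#' @export
community_emotion_index <- function(surface, communities,
                                    populations = "population",
                                    season = NA_character_) {
  stopifnot(inherits(surface, "density_surface"))
  if (is.character(populations) && length(populations) == 1) {
    populations <- communities[[populations]]
  }
  if (any(populations <= 0)) abort("Populations must be positive.")
  if (nrow(communities) == 0) abort("No communities supplied.")
  cells <- raster_cells(surface)
  assign <- nearest_index(
    cbind(cells$x, cells$y), cbind(communities$x, communities$y)
  )
  raw <- vapply(seq_len(nrow(communities)), function(i) {
    v <- cells$value[assign == i]
    if (length(v) == 0) {
      abort(sprintf(
        "Community %s has no covered grid cells; refine the grid.",
        communities$id[i]
      ))
    }
    mean(v)
  }, numeric(1))
  tibble(
    community_id = communities$id,
    season = season,
    raw_density = raw,
    population = populations,
    index = raw / (populations / 10000)
  )
}

#' Three-class sentiment classification metrics
#'
#' Confusion-matrix summary for the positive/neutral/negative label set:
#' overall accuracy, per-class precision, recall and F1, and their
#' unweighted macro averages. A class never predicted receives precision
#' 0 (and F1 0), so degenerate classifiers are not rewarded.
#'
#' @param true,predicted Character vectors of labels from
#'   `c("positive", "neutral", "negative")`.
#' @return A `classification_report`: list with `confusion` (3x3 matrix,
#'   rows = true), `accuracy`, `by_class` tibble, `macro` tibble row.
#' @export
classification_metrics <- function(true, predicted) {
  labs <- c("positive", "neutral", "negative")
  if (length(true) != length(predicted)) {
    abort("`true` and `predicted` must have equal length.")
  }
  bad <- setdiff(unique(c(true, predicted)), labs)
  if (length(bad) > 0) {
    abort(sprintf("Unknown labels: %s.", paste(bad, collapse = ", ")))
  }
  tf <- factor(true, levels = labs)
  pf <- factor(predicted, levels = labs)
  cm <- table(true = tf, predicted = pf)
  n <- sum(cm)
  acc <- sum(diag(cm)) / n
  prec <- vapply(labs, function(l) {
    denom <- sum(cm[, l])
    if (denom == 0) 0 else cm[l, l] / denom
  }, numeric(1))
  rec <- vapply(labs, function(l) {
    denom <- sum(cm[l, ])
    if (denom == 0) 0 else cm[l, l] / denom
  }, numeric(1))
  f1 <- ifelse(prec + rec == 0, 0, 2 * prec * rec / (prec + rec))
  by_class <- tibble(
    class = labs, precision = unname(prec), recall = unname(rec),
    f1 = unname(f1)
  )
  structure(
    list(
      confusion = unclass(cm),
      accuracy = acc,
      by_class = by_class,
      macro = tibble(
        precision = mean(prec), recall = mean(rec), f1 = mean(f1)
      )
    ),
    class = "classification_report"
  )
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report> accuracy %.3f\n", x$accuracy))
  print(x$by_class)
  invisible(x)
}

#' @export
tidy.classification_report <- function(x, ...) x$by_class

#' @export
glance.classification_report <- function(x, ...) {
  bind_cols(tibble(accuracy = x$accuracy), x$macro)
}
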