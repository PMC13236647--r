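# Shared fixtures, memoized so expensive objects are built once per run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# Small city for unit tests.
tiny_city <- function() {
  memo("tiny_city", generate_city(city_config(
    n_communities = 40, extent = c(8000, 8000), n_clusters = 4,
    cluster_sd = 1200, post_rate = 30, seed = 42
  )))
}

# The default study-condition city used by the acceptance properties.
default_city <- function() {
  memo("default_city", generate_city(city_config(seed = 101)))
}

default_annual_frame <- function() {
  memo("default_annual_frame", city_model_frame(default_city(), "annual"))
}

# Annual GWRF on the default city (300 trees: the analysis size used
# throughout the heavier checks).
default_gwrf <- function() {
  memo("default_gwrf", fit_gwrf(
    default_annual_frame(), bandwidth = 60, num_trees = 300, seed = 11
  ))
}

# A small frame from the tiny city for model unit tests.
tiny_frame <- function() {
  memo("tiny_frame", city_model_frame(tiny_city(), "annual"))
}

# Independent brute-force landscape metrics for small rasters: patch
# labels by iterative min-label propagation, edges by exhaustive
# adjacent-pair enumeration.
brute_landscape <- function(v, cell_size, connectivity = 8, nodata = -9999) {
  nr <- nrow(v); nc <- ncol(v)
  valid <- v != nodata & !is.na(v)
  lab <- matrix(seq_along(v), nr, nc)
  lab[!valid] <- 0L
  offs <- if (connectivity == 4) {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  } else {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
         c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  }
  repeat {
    changed <- FALSE
    for (i in seq_len(nr)) for (j in seq_len(nc)) {
      if (!valid[i, j]) next
      for (o in offs) {
        a <- i + o[1]; b <- j + o[2]
        if (a >= 1 && a <= nr && b >= 1 && b <= nc && valid[a, b] &&
            v[a, b] == v[i, j] && lab[a, b] < lab[i, j]) {
          lab[i, j] <- lab[a, b]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  patch_ids <- unique(lab[lab > 0])
  areas <- vapply(patch_ids, function(id) sum(lab == id) * cell_size^2, numeric(1))
  land <- sum(valid) * cell_size^2
  edge <- 0
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!valid[i, j]) next
    if (i < nr && valid[i + 1, j] && v[i + 1, j] != v[i, j]) edge <- edge + cell_size
    if (j < nc && valid[i, j + 1] && v[i, j + 1] != v[i, j]) edge <- edge + cell_size
  }
  pk <- tapply(
    rep(cell_size^2, sum(valid)), v[valid], sum
  )
  pk <- as.numeric(pk) / land
  list(
    n_patches = length(patch_ids),
    lpi = 100 * max(areas) / land,
    pd = length(patch_ids) / land * 1e6,
    ed = edge / (land / 1e4),
    shdi = -sum(pk * log(pk))
  )
}

# A density_surface with constant values, for indicator unit tests.
constant_surface <- function(value, extent, cell_size) {
  g <- grid_spec(extent, cell_size)
  r <- gm_raster(
    matrix(value, g$ny, g$nx), origin = g$origin, cell_size = cell_size
  )
  r$bandwidth <- 1
  r$kernel <- "quartic"
  r$n_events <- 0L
  class(r) <- c("density_surface", class(r))
  r
}
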