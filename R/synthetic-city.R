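# Synthetic city generator: communities, covariates, latent emotion,
# posts, and rasters with retained ground truth, so the full pipeline can
# be exercised and validated without external data.

#' Describe one factor's contribution to latent negative emotion
#'
#' The latent negative-emotion propensity of a community is an additive
#' function of its covariates. Each active factor contributes a
#' piecewise-linear term: a straight line with slope `slope`, optionally
#' bending at `threshold` to slope `slope_above` (this is how
#' direction-reversing "turning point" relationships are encoded). The
#' term can be scaled per effect-sign region (`region_sign`,
#' `region_scale`) and per season (`season_mult`), which is how the
#' generator creates spatially sign-varying and seasonally modulated
#' associations.
#'
#' @param factor Factor name (one of [factor_names()]).
#' @param slope Slope of the contribution below the threshold (or
#'   everywhere if `threshold` is `NULL`), per unit of the covariate.
#' @param threshold Covariate value at which the slope changes, or `NULL`
#'   for a purely linear term.
#' @param slope_above Slope above the threshold (required with
#'   `threshold`).
#' @param region_sign Sign (+1/-1) of the term in each effect region,
#'   recycled to the number of regions.
#' @param region_scale Positive magnitude multiplier per region, recycled.
#' @param season_mult Named (or length-4, season-ordered) positive
#'   multipliers applied in spring, summer, autumn, winter.
#' @return An `effect_term` list, to be assembled with [effect_spec()].
#' @export
effect_term <- function(factor, slope, threshold = NULL, slope_above = NULL,
                        region_sign = 1, region_scale = 1,
                        season_mult = c(spring = 1, summer = 1, autumn = 1, winter = 1)) {
  if (!factor %in% FACTOR_NAMES) {
    abort(sprintf("Unknown factor '%s'.", factor))
  }
  check_number(slope, "slope")
  if (!is.null(threshold)) {
    check_number(threshold, "threshold")
    if (is.null(slope_above)) abort("`slope_above` is required with `threshold`.")
    check_number(slope_above, "slope_above")
  }
  if (length(season_mult) == 4 && is.null(names(season_mult))) {
    names(season_mult) <- SEASONS
  }
  if (!all(SEASONS %in% names(season_mult))) {
    abort("`season_mult` must cover all four seasons.")
  }
  if (any(season_mult <= 0)) abort("Season multipliers must be positive.")
  if (any(region_scale <= 0)) abort("`region_scale` entries must be positive.")
  structure(
    list(
      factor = factor, slope = slope, threshold = threshold,
      slope_above = slope_above, region_sign = region_sign,
      region_scale = region_scale, season_mult = season_mult[SEASONS]
    ),
    class = "effect_term"
  )
}

#' @rdname effect_term
#' @param ... `effect_term` objects.
#' @export
effect_spec <- function(...) {
  terms <- list(...)
  if (length(terms) == 1 && is.list(terms[[1]]) && !inherits(terms[[1]], "effect_term")) {
    terms <- terms[[1]]
  }
  ok <- vapply(terms, inherits, logical(1), "effect_term")
  if (!all(ok)) abort("All arguments must be `effect_term` objects.")
  names(terms) <- vapply(terms, `[[`, character(1), "factor")
  structure(terms, class = "effect_spec")
}

#' Default generating effects of the synthetic city
#'
#' The default study conditions encode the qualitative structure the
#' pipeline is designed to detect:
#' * vegetation greenness (`ndvi`) has a V-shaped association with
#'   latent negative emotion that reverses direction at NDVI = 0.5, is
#'   strongest in spring and weakest in winter, and is much more salient
#'   in region 1 than region 2;
#' * green-space accessibility (`access_green`) has a linear association
#'   whose *sign flips between the two effect regions* (protective in
#'   region 1, adverse in region 2) and which dominates region 2;
#' * largest-patch index (`lpi`) bends from positive to negative at 40%;
#' * `openness` contributes a mild protective linear term;
#' * `lockdown` intensity raises latent negative emotion.
#'
#' All other factors are inert nuisance covariates.
#'
#' @return An [effect_spec()].
#' @export
default_effect_spec <- function() {
  effect_spec(
    effect_term("ndvi",
      slope = -2.8, threshold = 0.5, slope_above = 2.8,
      region_scale = c(1, 0.3),
      season_mult = c(spring = 1.3, summer = 1.0, autumn = 0.9, winter = 0.6)
    ),
    effect_term("access_green",
      slope = 0.09,
      region_sign = c(1, -1), region_scale = c(0.4, 1),
      season_mult = c(spring = 1.25, summer = 1.1, autumn = 0.9, winter = 0.7)
    ),
    effect_term("openness", slope = -0.25),
    effect_term("lpi",
      slope = 0.004, threshold = 40, slope_above = -0.004,
      season_mult = c(spring = 0.7, summer = 1.2, autumn = 1, winter = 1)
    ),
    effect_term("lockdown", slope = 0.5)
  )
}

# Per-factor marginal distribution used by the covariate sampler: target
# mean, spatial spread, persistent community-level spread (a community's
# deviation from the regional surface, e.g. its own vegetation stock),
# small season-to-season fluctuation, plausible range, and deterministic
# seasonal mean shifts (only greenness and lockdown vary by season).
factor_meta <- function() {
  m <- tibble(
    factor = FACTOR_NAMES,
    mean = c(0.5, 0.3, 10, 8, 0.5, 4, 40, 4, 0.8, 5, 0.45, 0.5, 30, 0.25),
    sd_spatial = c(0.12, 0.08, 4, 3.5, 0.12, 1.2, 15, 1.5, 0.25, 1.5, 0.15, 0.02, 12, 0.1),
    sd_noise = c(0.12, 0.05, 2, 1.8, 0.08, 0.8, 8, 1, 0.15, 1, 0.08, 0.02, 6, 0.05),
    sd_season = c(0.03, 0.02, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0.08),
    lo = c(0.02, 0, 0, 0, 0, 0, 0.5, 0.05, 0, 0.05, 0, 0.3, 0, 0),
    hi = c(0.98, 0.8, 40, 30, 1, 10, 100, 15, 2, 20, 1, 0.7, 63, 1),
    integer = FACTOR_NAMES %in% c("access_outdoor", "access_green"),
    seasonal = FACTOR_NAMES %in% c("ndvi", "gvi", "lockdown")
  )
  shifts <- list(
    ndvi = c(spring = 0.05, summer = 0.10, autumn = -0.03, winter = -0.12),
    gvi = c(spring = 0.02, summer = 0.05, autumn = -0.02, winter = -0.08),
    lockdown = c(spring = 0.20, summer = -0.10, autumn = -0.05, winter = 0.05)
  )
  attr(m, "season_shift") <- shifts
  m
}

# Random smooth scalar field over the extent: a sum of Gaussian bumps.
# Returned closure is deterministic; callers standardize its values over
# the points they evaluate.
make_smooth_field <- function(extent, n_bumps = 12) {
  cx <- runif(n_bumps, 0, extent[1])
  cy <- runif(n_bumps, 0, extent[2])
  w <- rnorm(n_bumps)
  sigma <- runif(n_bumps, 0.12, 0.35) * max(extent)
  function(x, y) {
    v <- numeric(length(x))
    for (k in seq_len(n_bumps)) {
      v <- v + w[k] * exp(-((x - cx[k])^2 + (y - cy[k])^2) / (2 * sigma[k]^2))
    }
    v
  }
}

#' Configure the synthetic city
#'
#' @param n_communities Number of communities (>= 10).
#' @param extent Width and height of the planar study area in meters.
#' @param n_regions Number of effect-sign regions (Voronoi cells of random
#'   region centers) across which effect terms may change sign or scale.
#' @param n_clusters,cluster_sd Parent count and Gaussian offspring spread
#'   (m) of the clustered community placement process.
#' @param post_rate Expected posts per community per season, before
#'   population scaling.
#' @param noise_sd Standard deviation of the homoscedastic Gaussian noise
#'   added to latent emotion per community and season.
#' @param effect_spec An [effect_spec()]; defaults to
#'   [default_effect_spec()].
#' @param negative_share_link Monotone function mapping latent emotion to
#'   the probability that a post is negative.
#' @param year Calendar year used for post timestamps; the winter season
#'   pools January, February and December of this same year.
#' @param seed Integer seed; identical configurations with identical
#'   seeds generate identical cities.
#' @return A `city_config` list.
#' @export
#' @examples
#' cfg <- city_config(n_communities = 40, seed = 7)
#' city <- generate_city(cfg)
#' city$communities
city_config <- function(n_communities = 300,
                        extent = c(30000, 30000),
                        n_regions = 2,
                        n_clusters = 8,
                        cluster_sd = 2500,
                        post_rate = 50,
                        noise_sd = 0.08,
                        effect_spec = default_effect_spec(),
                        negative_share_link = function(l) plogis(1.2 * (l - 1) - 0.8),
                        year = 2022,
                        seed = 101) {
  check_number(n_communities, "n_communities", positive = TRUE, integerish = TRUE)
  if (n_communities < 10) abort("`n_communities` must be at least 10.")
  if (length(extent) != 2 || any(!is.finite(extent)) || any(extent <= 0)) {
    abort("`extent` must be two positive lengths in meters.")
  }
  check_number(n_regions, "n_regions", positive = TRUE, integerish = TRUE)
  check_number(n_clusters, "n_clusters", positive = TRUE, integerish = TRUE)
  check_number(cluster_sd, "cluster_sd", positive = TRUE)
  if (!is.numeric(post_rate) || post_rate < 0) abort("`post_rate` must be >= 0.")
  if (!is.numeric(noise_sd) || noise_sd < 0) abort("`noise_sd` must be >= 0.")
  if (!inherits(effect_spec, "effect_spec")) abort("`effect_spec` must be an effect_spec().")
  if (!is.function(negative_share_link)) abort("`negative_share_link` must be a function.")
  check_number(seed, "seed", integerish = TRUE)
  structure(
    list(
      n_communities = as.integer(n_communities), extent = as.numeric(extent),
      n_regions = as.integer(n_regions), n_clusters = as.integer(n_clusters),
      cluster_sd = cluster_sd, post_rate = post_rate, noise_sd = noise_sd,
      effect_spec = effect_spec, negative_share_link = negative_share_link,
      year = as.integer(year), seed = as.integer(seed)
    ),
    class = "city_config"
  )
}

# Piecewise-linear contribution of one factor, centered so the term is 0
# at the threshold (or at the factor's nominal mean for linear terms).
term_value <- function(term, value, meta_mean) {
  if (is.null(term$threshold)) {
    term$slope * (value - meta_mean)
  } else {
    ifelse(
      value < term$threshold,
      term$slope * (value - term$threshold),
      term$slope_above * (value - term$threshold)
    )
  }
}

# Full contribution including region and season modulation.
contribution <- function(term, value, region, season, meta_mean, n_regions) {
  sgn <- rep_len(term$region_sign, n_regions)[region]
  scl <- rep_len(term$region_scale, n_regions)[region]
  sgn * scl * term$season_mult[[season]] * term_value(term, value, meta_mean)
}

#' Generate a synthetic city with known ground truth
#'
#' Places communities by a clustered point process, partitions the extent
#' into nearest-centroid (Voronoi) community polygons, draws 14
#' community-level covariates with smooth spatial gradients plus
#' independent noise, assigns effect-sign regions, and computes latent
#' negative emotion per community and season from the configured effect
#' specification. The generating functions are retained in `$truth` so
#' recovery tests can compare fitted quantities against them.
#'
#' @param config A [city_config()].
#' @return A `synthetic_city` object with elements `communities` (tibble:
#'   id, x, y, region, boundary_dist, population, area, polygon),
#'   `covariates` (tibble: community_id, season, 14 factor columns),
#'   `latent` (tibble: community_id, season, latent), `config`, and
#'   `truth` (effect spec, noiseless latent function, vegetated-zone
#'   field).
#' @export
generate_city <- function(config) {
  if (!inherits(config, "city_config")) abort("`config` must be a city_config().")
  n <- config$n_communities
  ext <- config$extent
  with_seed(config$seed, {
    # -- community placement: Thomas-style cluster process + background --
    n_bg <- max(1L, round(0.15 * n))
    n_cl <- n - n_bg
    parents <- cbind(
      runif(config$n_clusters, 0.15 * ext[1], 0.85 * ext[1]),
      runif(config$n_clusters, 0.15 * ext[2], 0.85 * ext[2])
    )
    pick <- sample.int(config$n_clusters, n_cl, replace = TRUE)
    pts <- rbind(
      cbind(
        rnorm(n_cl, parents[pick, 1], config$cluster_sd),
        rnorm(n_cl, parents[pick, 2], config$cluster_sd)
      ),
      cbind(runif(n_bg, 0, ext[1]), runif(n_bg, 0, ext[2]))
    )
    pts[, 1] <- pmin(pmax(pts[, 1], 0.01 * ext[1]), 0.99 * ext[1])
    pts[, 2] <- pmin(pmax(pts[, 2], 0.01 * ext[2]), 0.99 * ext[2])
    # Communities keep a minimum separation (0.3x the mean spacing), so
    # no Voronoi footprint degenerates into a sliver smaller than an
    # analysis grid cell.
    pts <- enforce_min_separation(pts, ext, 0.3 * sqrt(prod(ext) / n))

    # -- effect regions: Voronoi of random region centers --
    rc <- cbind(
      runif(config$n_regions, 0.2 * ext[1], 0.8 * ext[1]),
      runif(config$n_regions, 0.2 * ext[2], 0.8 * ext[2])
    )
    dreg <- cross_dist(pts, rc)
    region <- max.col(-dreg, ties.method = "first")
    boundary_dist <- if (config$n_regions > 1) {
      apply(dreg, 1, function(d) {
        s <- sort(d, partial = 1:2)
        (s[2] - s[1]) / 2 # distance to the bisector with the runner-up
      })
    } else {
      rep(Inf, n)
    }

    population <- pmax(500, round(rlnorm(n, meanlog = log(8000), sdlog = 0.5)))

    polys <- voronoi_polygons(pts, ext)
    area <- vapply(polys, polygon_area, numeric(1))

    communities <- tibble(
      id = seq_len(n),
      x = pts[, 1], y = pts[, 2],
      region = region,
      boundary_dist = boundary_dist,
      population = population,
      area = area,
      polygon = polys
    )

    # -- covariates: smooth spatial field + independent noise, per factor --
    meta <- factor_meta()
    shifts <- attr(meta, "season_shift")
    fields <- lapply(seq_len(nrow(meta)), function(i) make_smooth_field(ext))
    base_spatial <- lapply(fields, function(f) {
      v <- f(pts[, 1], pts[, 2])
      as.numeric(scale(v))
    })
    static_noise <- lapply(seq_len(nrow(meta)), function(i) {
      rnorm(n, 0, meta$sd_noise[i])
    })
    covariates <- bind_rows(lapply(SEASONS, function(s) {
      vals <- lapply(seq_len(nrow(meta)), function(i) {
        mi <- meta[i, ]
        shift <- if (mi$seasonal) shifts[[mi$factor]][[s]] else 0
        wobble <- if (mi$sd_season > 0) rnorm(n, 0, mi$sd_season) else 0
        v <- mi$mean + shift + mi$sd_spatial * base_spatial[[i]] +
          static_noise[[i]] + wobble
        v <- pmin(pmax(v, mi$lo), mi$hi)
        if (mi$integer) v <- round(v)
        v
      })
      names(vals) <- meta$factor
      bind_cols(tibble(community_id = seq_len(n), season = s), as_tibble(vals))
    }))

    # -- latent emotion from the effect spec --
    meta_means <- setNames(meta$mean, meta$factor)
    latent_fn <- make_latent_fn(config$effect_spec, meta_means, config$n_regions)
    noiseless <- latent_fn(covariates, region[covariates$community_id],
      covariates$season)
    noise <- rnorm(nrow(covariates), 0, config$noise_sd)
    latent <- tibble(
      community_id = covariates$community_id,
      season = covariates$season,
      latent = noiseless + noise
    )

    vegetated_field <- make_smooth_field(ext)

    structure(
      list(
        communities = communities,
        covariates = covariates,
        latent = latent,
        config = config,
        truth = list(
          effect_spec = config$effect_spec,
          meta_means = meta_means,
          latent_fn = latent_fn,
          region_centers = rc,
          vegetated_field = vegetated_field
        )
      ),
      class = "synthetic_city"
    )
  })
}

# Build the noiseless latent-emotion function implied by an effect spec.
# `covars` is a data frame with factor columns; region and season are
# vectors aligned to its rows.
make_latent_fn <- function(spec, meta_means, n_regions, intercept = 1) {
  force(spec); force(meta_means); force(n_regions); force(intercept)
  function(covars, region, season) {
    out <- rep(intercept, nrow(covars))
    for (term in spec) {
      mm <- meta_means[[term$factor]]
      sgn <- rep_len(term$region_sign, n_regions)[region]
      scl <- rep_len(term$region_scale, n_regions)[region]
      smult <- unlist(term$season_mult)[season]
      out <- out + sgn * scl * smult * term_value(term, covars[[term$factor]], mm)
    }
    unname(out)
  }
}

#' @export
print.synthetic_city <- function(x, ...) {
  cat(sprintf(
    "<synthetic_city> %d communities, %d regions, extent %g x %g m\n",
    nrow(x$communities), x$config$n_regions,
    x$config$extent[1], x$config$extent[2]
  ))
  invisible(x)
}

#' Generate geotagged posts for one season
#'
#' Per community, the post count is Poisson with mean
#' `post_rate * (population / mean population) * (area / mean area)`:
#' geotagged activity scales with how many residents post and with the
#' spatial footprint over which check-ins accrue. (This also makes the
#' KDE-then-population-standardize indicator identifiable for latent
#' emotion, the property the pipeline assumes of real check-in data.)
#' Post locations are uniform within the community polygon; each post is
#' labeled negative with probability
#' `negative_share_link(latent_emotion)` and otherwise split evenly
#' between positive and neutral. Timestamps are uniform
#' within the season's months (the winter window pools January, February
#' and December of the configured year).
#'
#' @param city A [generate_city()] result.
#' @param season One of `"spring"`, `"summer"`, `"autumn"`, `"winter"`.
#' @param seed Integer seed.
#' @return A tibble of posts: `id`, `community_id`, `x`, `y`,
#'   `timestamp` (UTC), `sentiment`.
#' @export
generate_posts <- function(city, season, seed = 1) {
  stopifnot(inherits(city, "synthetic_city"))
  check_season(season)
  cfg <- city$config
  com <- city$communities
  lat <- city$latent[city$latent$season == season, ]
  lat <- lat[match(com$id, lat$community_id), ]
  with_seed(seed, {
    mean_pop <- mean(com$population)
    mean_area <- mean(com$area)
    counts <- rpois(
      nrow(com),
      cfg$post_rate * (com$population / mean_pop) * (com$area / mean_area)
    )
    if (sum(counts) == 0) {
      return(tibble(
        id = integer(), community_id = integer(), x = numeric(),
        y = numeric(), timestamp = as.POSIXct(character(), tz = "UTC"),
        sentiment = character()
      ))
    }
    p_neg <- cfg$negative_share_link(lat$latent)
    months <- switch(season,
      spring = 3:5, summer = 6:8, autumn = 9:11, winter = c(1, 2, 12)
    )
    t0 <- as.POSIXct(sprintf("%d-%02d-01 00:00:00", cfg$year, months), tz = "UTC")
    t1 <- as.POSIXct(
      sprintf(
        "%d-%02d-01 00:00:00",
        cfg$year + (months == 12), (months %% 12) + 1
      ),
      tz = "UTC"
    )
    posts <- lapply(which(counts > 0), function(i) {
      k <- counts[i]
      xy <- sample_in_polygon(com$polygon[[i]], k, com[, c("x", "y")], i)
      neg <- runif(k) < p_neg[i]
      other <- sample(c("positive", "neutral"), k, replace = TRUE)
      mo <- sample.int(length(months), k, replace = TRUE)
      ts <- t0[mo] + runif(k) * as.numeric(difftime(t1[mo], t0[mo], units = "secs"))
      tibble(
        community_id = com$id[i], x = xy[, 1], y = xy[, 2],
        timestamp = ts,
        sentiment = ifelse(neg, "negative", other)
      )
    })
    out <- bind_rows(posts)
    out <- bind_cols(tibble(id = seq_len(nrow(out))), out)
    out
  })
}

# Uniform samples inside a community polygon by rejection from its
# bounding box; membership is nearest-centroid, which is what defines the
# polygon in the first place.
sample_in_polygon <- function(poly, k, centers, own) {
  bb <- apply(poly, 2, range)
  centers <- as.matrix(centers)
  out <- matrix(numeric(0), 0, 2)
  while (nrow(out) < k) {
    m <- max(2L * (k - nrow(out)), 16L)
    cand <- cbind(runif(m, bb[1, 1], bb[2, 1]), runif(m, bb[1, 2], bb[2, 2]))
    keep <- nearest_index(cand, centers) == own
    out <- rbind(out, cand[keep, , drop = FALSE])
  }
  out[seq_len(k), , drop = FALSE]
}

#' Generate a land-use class raster
#'
#' Classes are carved out of a smooth random field by quantile breaks, so
#' each class forms contiguous patches and realized class proportions
#' track `proportions`.
#'
#' @param city A [generate_city()] result (defines the extent).
#' @param n_classes Number of land-use classes (>= 1).
#' @param cell_size Cell size in meters; must not exceed the extent.
#' @param seed Integer seed.
#' @param proportions Target class proportions (default equal); recycled
#'   and normalized.
#' @return A [gm_raster()] of integer classes 1..n_classes.
#' @export
generate_landuse <- function(city, n_classes = 4, cell_size = 100, seed = 1,
                             proportions = NULL) {
  stopifnot(inherits(city, "synthetic_city"))
  check_number(n_classes, "n_classes", positive = TRUE, integerish = TRUE)
  check_number(cell_size, "cell_size", positive = TRUE)
  ext <- city$config$extent
  if (cell_size > min(ext)) abort("`cell_size` exceeds the city extent.")
  if (is.null(proportions)) proportions <- rep(1 / n_classes, n_classes)
  proportions <- rep_len(proportions, n_classes)
  proportions <- proportions / sum(proportions)
  nx <- max(1L, floor(ext[1] / cell_size))
  ny <- max(1L, floor(ext[2] / cell_size))
  with_seed(seed, {
    f <- make_smooth_field(ext, n_bumps = 20)
    g <- raster_grid_coords(nx, ny, cell_size)
    v <- f(g$x, g$y) + rnorm(length(g$x), 0, 0.02)
    if (n_classes == 1) {
      cls <- rep(1L, length(v))
    } else {
      brk <- quantile(v, probs = cumsum(proportions)[-n_classes])
      cls <- findInterval(v, brk) + 1L
    }
    gm_raster(matrix(as.integer(cls), nrow = ny, ncol = nx),
      origin = c(0, 0), cell_size = cell_size
    )
  })
}

#' Generate a two-band (NIR, red) reflectance raster pair
#'
#' Reflectances lie in \[0, 1\]. Inside the city's vegetated zones (the
#' upper half of a stored smooth field) near-infrared reflectance is
#' elevated well above red, so the downstream normalized difference
#' vegetation index is positive there.
#'
#' @inheritParams generate_landuse
#' @return A list with `nir` and `red` [gm_raster()]s and `vegetated`, a
#'   0/1 mask raster of the generating vegetated zone.
#' @export
generate_reflectance <- function(city, cell_size = 100, seed = 1) {
  stopifnot(inherits(city, "synthetic_city"))
  check_number(cell_size, "cell_size", positive = TRUE)
  ext <- city$config$extent
  nx <- max(1L, floor(ext[1] / cell_size))
  ny <- max(1L, floor(ext[2] / cell_size))
  g <- raster_grid_coords(nx, ny, cell_size)
  f <- city$truth$vegetated_field
  v <- f(g$x, g$y)
  veg <- v > median(v)
  with_seed(seed, {
    nir <- ifelse(veg, 0.55, 0.30) + rnorm(length(v), 0, 0.04)
    red <- ifelse(veg, 0.08, 0.28) + rnorm(length(v), 0, 0.03)
    clamp01 <- function(z) pmin(pmax(z, 0), 1)
    list(
      nir = gm_raster(matrix(clamp01(nir), ny, nx), c(0, 0), cell_size),
      red = gm_raster(matrix(clamp01(red), ny, nx), c(0, 0), cell_size),
      vegetated = gm_raster(matrix(as.integer(veg), ny, nx), c(0, 0), cell_size)
    )
  })
}

# Iterative pair repulsion until all centroids are at least `delta`
# apart (clipped to the extent). Preserves the clustered structure while
# removing sliver polygons.
enforce_min_separation <- function(pts, ext, delta, max_iter = 60) {
  for (it in seq_len(max_iter)) {
    d <- cross_dist(pts, pts)
    diag(d) <- Inf
    bad <- which(d < delta, arr.ind = TRUE)
    bad <- bad[bad[, 1] < bad[, 2], , drop = FALSE]
    if (nrow(bad) == 0) break
    for (r in seq_len(nrow(bad))) {
      i <- bad[r, 1]
      j <- bad[r, 2]
      v <- pts[j, ] - pts[i, ]
      dv <- sqrt(sum(v^2))
      if (dv < 1e-9) {
        v <- c(1, 0)
        dv <- 1
      }
      push <- (delta - dv) / 2 + 0.01 * delta
      pts[i, ] <- pts[i, ] - v / dv * push
      pts[j, ] <- pts[j, ] + v / dv * push
    }
    pts[, 1] <- pmin(pmax(pts[, 1], 0.01 * ext[1]), 0.99 * ext[1])
    pts[, 2] <- pmin(pmax(pts[, 2], 0.01 * ext[2]), 0.99 * ext[2])
  }
  pts
}

# Cell-center coordinates for a ny x nx raster stored top-row-first.
raster_grid_coords <- function(nx, ny, cell_size) {
  xs <- (seq_len(nx) - 0.5) * cell_size
  ys <- (ny - seq_len(ny) + 0.5) * cell_size
  list(x = rep(xs, each = ny), y = rep(ys, times = nx))
}
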