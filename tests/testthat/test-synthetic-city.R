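# The synthetic city generator: determinism, ground-truth retention,
# and the statistical structure downstream stages rely on.

test_that("city generation is deterministic and validates its config", {
  cfg <- city_config(n_communities = 20, extent = c(5000, 5000), seed = 3)
  a <- generate_city(cfg)
  b <- generate_city(cfg)
  expect_identical(a$communities, b$communities)
  expect_identical(a$covariates, b$covariates)
  expect_identical(a$latent, b$latent)

  expect_error(city_config(n_communities = 5), "at least 10")
  expect_error(city_config(extent = c(-1, 100)), "positive")
  expect_error(
    effect_term("ndvi", 1, season_mult = c(spring = 1, summer = -1, autumn = 1, winter = 1)),
    "positive"
  )
  expect_error(effect_term("not_a_factor", 1), "Unknown factor")
})

test_that("communities are complete, partitioned into regions, and tile the extent", {
  city <- tiny_city()
  cov <- city$covariates
  expect_equal(nrow(cov), 40 * 4)
  expect_false(anyNA(cov[, factor_names()]))
  expect_setequal(unique(cov$season), seasons())
  expect_true(all(city$communities$region %in% seq_len(city$config$n_regions)))
  # Voronoi polygons partition the extent
  expect_equal(sum(city$communities$area), 8000 * 8000, tolerance = 1e-6)
  # ranges honour the factor semantics
  expect_true(all(cov$ndvi >= -1 & cov$ndvi <= 1))
  expect_true(all(cov$gvi >= 0 & cov$gvi <= 1))
  expect_true(all(cov$lockdown >= 0 & cov$lockdown <= 1))
  expect_true(all(city$communities$population >= 500))
})

test_that("zero slopes and zero noise give constant latent emotion", {
  cfg <- city_config(
    n_communities = 15, extent = c(4000, 4000), noise_sd = 0,
    effect_spec = effect_spec(), seed = 9
  )
  city <- generate_city(cfg)
  expect_equal(var(city$latent$latent), 0)
})

test_that("stored truth reproduces region-dependent effect signs (finite differences)", {
  spec <- effect_spec(
    effect_term("access_green", slope = 1, region_sign = c(1, -1))
  )
  cfg <- city_config(
    n_communities = 30, extent = c(6000, 6000), n_regions = 2,
    noise_sd = 0, effect_spec = spec, seed = 17
  )
  city <- generate_city(cfg)
  cov <- city$covariates[city$covariates$season == "spring", ]
  base <- city$truth$latent_fn(cov, city$communities$region, cov$season)
  bumped <- cov
  bumped$access_green <- bumped$access_green + 1
  up <- city$truth$latent_fn(bumped, city$communities$region, cov$season)
  fd_sign <- sign(up - base)
  expect_equal(unname(fd_sign), ifelse(city$communities$region == 1, 1, -1))
  # and the stored latent matches the truth function exactly (noise 0)
  expect_equal(city$latent$latent[city$latent$season == "spring"], base)
})

test_that("post generation honours rate, link, season window and polygons", {
  city <- tiny_city()
  none <- generate_posts(
    generate_city(city_config(
      n_communities = 12, extent = c(3000, 3000), post_rate = 0, seed = 1
    )),
    "spring",
    seed = 2
  )
  expect_equal(nrow(none), 0)

  all_neg_city <- generate_city(city_config(
    n_communities = 12, extent = c(3000, 3000), post_rate = 20,
    negative_share_link = function(l) rep(1, length(l)), seed = 4
  ))
  p <- generate_posts(all_neg_city, "autumn", seed = 5)
  expect_true(all(p$sentiment == "negative"))
  expect_true(all(assign_season(p$timestamp) == "autumn"))

  expect_error(generate_posts(city, "monsoon", seed = 1), "season")

  p2 <- generate_posts(city, "winter", seed = 7)
  expect_identical(p2, generate_posts(city, "winter", seed = 7))
  # winter pools Jan/Feb/Dec of the configured year
  expect_setequal(
    unique(as.integer(format(p2$timestamp, "%m"))), c(1L, 2L, 12L)
  )
  expect_true(all(format(p2$timestamp, "%Y") == "2022"))
  # every post lies inside its community's nearest-centroid cell
  centers <- as.matrix(city$communities[, c("x", "y")])
  near <- apply(
    (outer(p2$x, centers[, 1], "-"))^2 + (outer(p2$y, centers[, 2], "-"))^2,
    1, which.min
  )
  expect_equal(near, p2$community_id)
})

test_that("empirical negative shares match the link within Monte-Carlo error", {
  cfg <- city_config(
    n_communities = 60, extent = c(12000, 12000), noise_sd = 0,
    post_rate = 400, seed = 31
  )
  city <- generate_city(cfg)
  p <- generate_posts(city, "summer", seed = 8)
  lat <- city$latent[city$latent$season == "summer", ]
  p_true <- cfg$negative_share_link(lat$latent)
  emp <- p |>
    dplyr::group_by(community_id) |>
    dplyr::summarise(share = mean(sentiment == "negative"), n = dplyr::n())
  emp <- emp[match(lat$community_id, emp$community_id), ]
  se <- sqrt(p_true * (1 - p_true) / emp$n)
  within3 <- abs(emp$share - p_true) <= 3 * se
  # 3 sigma per community: allow for the expected handful of exceedances
  expect_gte(mean(within3), 57 / 60)
})

test_that("land-use rasters honour class count, proportions and determinism", {
  city <- tiny_city()
  one <- generate_landuse(city, n_classes = 1, cell_size = 400, seed = 2)
  expect_true(all(one$values == 1))

  a <- generate_landuse(city, n_classes = 3, cell_size = 200, seed = 6)
  b <- generate_landuse(city, n_classes = 3, cell_size = 200, seed = 6)
  expect_identical(a$values, b$values)

  two <- generate_landuse(city, n_classes = 2, cell_size = 100, seed = 3,
    proportions = c(0.5, 0.5))
  props <- as.numeric(table(two$values)) / length(two$values)
  expect_true(all(abs(props - 0.5) <= 0.05))
  # each class forms at least one patch
  ps <- delineate_patches(two)
  expect_setequal(unique(ps$patches$class), c(1L, 2L))

  expect_error(generate_landuse(city, cell_size = 1e6), "extent")
})

test_that("reflectance pairs put NIR above red inside vegetated zones", {
  city <- tiny_city()
  rp <- generate_reflectance(city, cell_size = 200, seed = 5)
  expect_identical(rp$nir$values,
    generate_reflectance(city, cell_size = 200, seed = 5)$nir$values)
  expect_true(all(rp$nir$values >= 0 & rp$nir$values <= 1))
  expect_true(all(rp$red$values >= 0 & rp$red$values <= 1))
  nd <- ndvi(rp$nir, rp$red)
  veg <- rp$vegetated$values == 1
  expect_gt(mean(nd$values[veg]), mean(nd$values[!veg]))
})
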