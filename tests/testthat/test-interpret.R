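# Partial dependence, turning-point detection, local dominant factors,
# and signed local effect surfaces.

test_that("partial dependence is flat for ignored factors and linear for identity", {
  X <- data.frame(a = runif(40), b = runif(40))
  f_ignore <- function(d) 2 * d$b
  pd <- partial_dependence(f_ignore, X, "a", grid_size = 8)
  expect_lt(diff(range(pd$estimate)), 1e-12)

  f_id <- function(d) d$a
  pd2 <- partial_dependence(f_id, X, "a", grid_size = 8)
  expect_equal(pd2$estimate, pd2$grid)
  expect_true(all(pd2$band == 0))

  Xc <- data.frame(a = rep(0.5, 10), b = runif(10))
  expect_warning(pdc <- partial_dependence(f_id, Xc, "a"), "constant")
  expect_equal(nrow(pdc), 1)
})

test_that("turning points are located at interior slope sign changes", {
  g <- seq(0, 1, length.out = 21)
  v_curve <- tibble::tibble(factor = "f", grid = g, estimate = abs(g - 0.48),
    band = 0)
  expect_equal(find_turning_point(v_curve, "min"), g[which.min(abs(g - 0.48))])
  expect_equal(find_turning_point(v_curve, "auto"), g[which.min(abs(g - 0.48))])

  peak <- tibble::tibble(factor = "f", grid = g, estimate = -(g - 0.7)^2, band = 0)
  expect_equal(find_turning_point(peak, "auto"), g[which.max(-(g - 0.7)^2)])

  mono <- tibble::tibble(factor = "f", grid = g, estimate = g, band = 0)
  expect_true(is.na(find_turning_point(mono, "min")))
})

test_that("globally linear positive effects give positive local slopes everywhere", {
  spec <- effect_spec(effect_term("access_green", slope = 0.1))
  city <- generate_city(city_config(
    n_communities = 50, extent = c(9000, 9000), noise_sd = 0.02,
    effect_spec = spec, seed = 23
  ))
  fr <- city_model_frame(city, "annual")
  gw <- fit_gwrf(fr, bandwidth = 30, num_trees = 100, min_local = 20, seed = 6)
  eff <- local_effect_surface(gw, "access_green")
  expect_true(all(eff$sign == 1))
  expect_error(local_effect_surface(gw, "nope"), "Unknown factor")
})

test_that("standardized local effects shrink as generator noise grows", {
  spec <- effect_spec(effect_term("access_green", slope = 0.1))
  mk <- function(noise) {
    city <- generate_city(city_config(
      n_communities = 50, extent = c(9000, 9000), noise_sd = noise,
      effect_spec = spec, seed = 23
    ))
    fr <- city_model_frame(city, "annual")
    gw <- fit_gwrf(fr, bandwidth = 30, num_trees = 100, min_local = 20, seed = 6)
    # association strength relative to the response scale: raw slopes
    # grow with any added response variance, standardized ones attenuate
    median(abs(local_effect_surface(gw, "access_green")$slope)) / sd(fr$y)
  }
  expect_gt(mk(0.02), mk(2))
})

test_that("dominant factors are tabulated with shares summing to 100", {
  # two regions driven by different single factors
  spec <- effect_spec(
    effect_term("ndvi", slope = 2, region_scale = c(1, 0.05)),
    effect_term("access_green", slope = 0.12, region_scale = c(0.05, 1))
  )
  city <- generate_city(city_config(
    n_communities = 60, extent = c(10000, 10000), noise_sd = 0.02,
    effect_spec = spec, seed = 33
  ))
  fr <- city_model_frame(city, "annual")
  gw <- fit_gwrf(fr, bandwidth = 30, num_trees = 100, min_local = 20, seed = 6)
  dom <- local_dominant_factors(gw, seed = 9)
  expect_equal(sum(dom$shares$share_pct), 100)
  expect_equal(nrow(dom$communities), 60)
  # deterministic under fixed seeds
  dom2 <- local_dominant_factors(gw, seed = 9)
  expect_identical(dom$communities, dom2$communities)
  # the regional drivers carry the map off the boundary
  com <- city$communities
  off <- com$boundary_dist > 1000
  driver <- ifelse(com$region == 1, "ndvi", "access_green")
  expect_gte(mean((dom$communities$dominant_factor == driver)[off]), 0.6)
})
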