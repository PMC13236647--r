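# Season assignment, seasonal event filtering, the KDE surface, the
# population-standardized indicator, and classification metrics.

test_that("timestamps map to meteorological seasons, partitioning the year", {
  expect_equal(assign_season(as.Date("2022-04-15")), "spring")
  expect_equal(assign_season(as.Date("2022-12-25")), "winter")
  expect_equal(assign_season(as.Date("2022-03-01")), "spring") # boundary day
  months <- as.Date(sprintf("2022-%02d-15", 1:12))
  s <- assign_season(months)
  expect_false(anyNA(s))
  expect_equal(as.vector(table(s)[seasons()]), rep(3L, 4))
  expect_error(assign_season("not a date"), "parse")
})

test_that("negative_events filters by label and season", {
  posts <- tibble::tibble(
    x = 1:10, y = 1:10,
    timestamp = as.POSIXct(sprintf("2022-%02d-10", c(4, 4, 7, 12, 1, 4, 7, 9, 10, 5)), tz = "UTC"),
    sentiment = c("negative", "negative", "negative", "negative",
                  "positive", "neutral", "positive", "neutral", "positive", "neutral")
  )
  expect_equal(nrow(negative_events(posts, "spring")), 2) # April negatives
  expect_equal(nrow(negative_events(posts, "summer")), 1)
  expect_equal(nrow(negative_events(posts, "winter")), 1)
  expect_equal(nrow(negative_events(posts, "autumn")), 0)
})

test_that("KDE matches the closed form at a single event and has finite support", {
  g <- grid_spec(c(10, 10), 0.05)
  # event placed exactly on a cell center
  s <- kde_surface(data.frame(x = 5.025, y = 5.025), g, bandwidth = 1)
  expect_equal(max(s$values), 3 / pi, tolerance = 1e-12)
  # quartic kernel: zero beyond one bandwidth
  cells <- raster_cells(s)
  far <- sqrt((cells$x - 5.025)^2 + (cells$y - 5.025)^2) > 1
  expect_true(all(cells$value[far] == 0))
  expect_error(kde_surface(data.frame(x = numeric(), y = numeric()), g, 1), "empty")
  expect_error(kde_surface(data.frame(x = 1, y = 1), g, -2), "positive")
})

test_that("interior KDE mass is conserved for all kernels", {
  h <- 1
  g <- grid_spec(c(20, 20), h / 20)
  ev <- data.frame(x = c(8, 10, 12, 9.5, 11), y = c(10, 8, 12, 11, 9))
  for (k in c("quartic", "uniform", "gaussian")) {
    s <- kde_surface(ev, g, h, kernel = k)
    mass <- sum(s$values) * (h / 20)^2
    expect_gt(mass, 0.99)
    expect_lt(mass, 1.01)
  }
})

test_that("adding an interior event never decreases a community's density", {
  city <- tiny_city()
  g <- grid_spec(city$config$extent, 250)
  ev <- as.data.frame(city$communities[1:20, c("x", "y")])
  s1 <- kde_surface(ev, g, bandwidth = 900)
  idx1 <- community_emotion_index(s1, city$communities)
  # drop one more event on community 3's centroid
  ev2 <- rbind(ev, as.data.frame(city$communities[3, c("x", "y")]))
  s2 <- kde_surface(ev2, g, bandwidth = 900)
  idx2 <- community_emotion_index(s2, city$communities)
  # surfaces renormalize by n, so compare unnormalized sums
  expect_gte(
    idx2$raw_density[3] * nrow(ev2), idx1$raw_density[3] * nrow(ev)
  )
})

test_that("indicator standardization follows the per-10,000-residents convention", {
  coms <- tibble::tibble(id = 1:4, x = c(1, 3, 1, 3) * 250,
    y = c(1, 1, 3, 3) * 250, population = rep(10000, 4))
  s0 <- constant_surface(0, c(1000, 1000), 100)
  idx0 <- community_emotion_index(s0, coms)
  expect_true(all(idx0$index == 0))

  s <- constant_surface(0.5, c(1000, 1000), 100)
  idx <- community_emotion_index(s, coms)
  expect_equal(idx$raw_density, rep(0.5, 4))
  expect_equal(idx$index, rep(0.5, 4)) # pop 10,000 -> index == raw density
  idx2 <- community_emotion_index(s, coms, populations = coms$population * 2)
  expect_equal(idx2$index, idx$index / 2) # doubling population halves indices

  expect_error(community_emotion_index(s, coms, populations = rep(0, 4)), "positive")
  coarse <- constant_surface(1, c(1000, 1000), 1000) # one cell for 4 communities
  expect_error(community_emotion_index(coarse, coms), "covered")
})

test_that("the indicator recovers latent emotion on noiseless synthetic data", {
  cfg <- city_config(
    n_communities = 60, extent = c(12000, 12000), noise_sd = 0,
    post_rate = 400, seed = 31
  )
  city <- generate_city(cfg)
  posts <- generate_posts(city, "summer", seed = 8)
  ev <- negative_events(posts, "summer")
  s <- kde_surface(ev, grid_spec(c(12000, 12000), 100), bandwidth = 150)
  idx <- community_emotion_index(s, city$communities, season = "summer")
  lat <- city$latent[city$latent$season == "summer", ]
  lat <- lat[match(idx$community_id, lat$community_id), ]
  expect_gte(cor(idx$index, lat$latent, method = "spearman"), 0.9)
})

test_that("classification metrics reproduce hand-computed confusion summaries", {
  labs <- c("negative", "neutral", "positive")
  ident <- classification_metrics(labs, labs)
  expect_equal(ident$accuracy, 1)
  expect_true(all(ident$by_class$f1 == 1))

  true <- c("negative", "negative", "positive", "neutral")
  pred <- c("negative", "positive", "positive", "neutral")
  rep_ <- classification_metrics(true, pred)
  expect_equal(rep_$accuracy, 0.75)
  neg <- rep_$by_class[rep_$by_class$class == "negative", ]
  expect_equal(neg$precision, 1)
  expect_equal(neg$recall, 0.5)
  expect_equal(neg$f1, 2 / 3)
  expect_equal(sum(rep_$confusion), 4)

  # permutation invariance
  o <- c(3, 1, 4, 2)
  rep_p <- classification_metrics(true[o], pred[o])
  expect_equal(rep_p$by_class, rep_$by_class)

  # never-predicted class gets precision 0, not NaN
  rep_n <- classification_metrics(
    c("negative", "positive"), c("positive", "positive")
  )
  neu <- rep_n$by_class[rep_n$by_class$class == "neutral", ]
  expect_equal(neu$precision, 0)

  expect_error(classification_metrics("negative", c("negative", "neutral")), "length")
  expect_error(classification_metrics("negative", "angry"), "Unknown")
})
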