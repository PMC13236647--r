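# The three models and their shared evaluation metrics.

test_that("evaluation metrics match hand-computed values and identities", {
  m <- evaluate_predictions(c(1, 2, 3), c(1, 2, 4))
  expect_equal(m$r_squared, 0.5)
  expect_equal(m$mae, 1 / 3)
  expect_equal(m$rmse, sqrt(1 / 3))

  y <- rnorm(50)
  ident <- evaluate_predictions(y, y)
  expect_equal(ident$r_squared, 1)
  expect_equal(ident$mae, 0)
  expect_equal(evaluate_predictions(y, rep(mean(y), 50))$r_squared, 0)

  yhat <- y + rnorm(50)
  m2 <- evaluate_predictions(y, yhat)
  expect_gte(m2$rmse, m2$mae)
  # common positive affine transform leaves R^2 unchanged
  m3 <- evaluate_predictions(2 * y + 1, 2 * yhat + 1)
  expect_equal(m3$r_squared, m2$r_squared)

  expect_error(evaluate_predictions(1:3, 1:2), "length")
  expect_error(evaluate_predictions(c(1, 1), c(1, 2)), "sum of squares")
})

test_that("the global forest is deterministic and fits strong signal", {
  fr <- tiny_frame()
  f1 <- fit_global_rf(fr, num_trees = 100, seed = 3)
  f2 <- fit_global_rf(fr, num_trees = 100, seed = 3)
  expect_identical(predict(f1), predict(f2))

  const <- fr
  const$y <- rep(2.5, length(fr$y))
  expect_warning(fc <- fit_global_rf(const, num_trees = 50, seed = 1), "variance")
  expect_true(all(predict(fc) == 2.5))

  # noiseless nonlinear signal, 500 samples: in-sample R^2 > 0.9
  set.seed(8)
  X <- tibble::tibble(ndvi = runif(500), gvi = runif(500), lpi = runif(500, 0, 100))
  y <- 3 * abs(X$ndvi - 0.5) + 0.01 * X$lpi
  d <- dplyr::bind_cols(tibble::tibble(latent = y, x = runif(500), y0 = runif(500)), X)
  names(d)[names(d) == "y0"] <- "y"
  frx <- model_frame(d, response = "latent", factors = c("ndvi", "gvi", "lpi"))
  fx <- fit_global_rf(frx, num_trees = 300, seed = 2)
  expect_gt(evaluate_predictions(frx$y, predict(fx))$r_squared, 0.9)
})

test_that("GWR recovers exact global-linear structure at any bandwidth", {
  fr <- tiny_frame()
  lin <- fr
  lin$y <- 0.7 + 2 * fr$X$ndvi - 0.3 * fr$X$openness
  for (bw in c(20, 30, length(lin$y))) {
    g <- fit_gwr(lin, bandwidth = bw)
    expect_lt(max(abs(g$coefficients[, "ndvi"] - 2)), 1e-8)
    expect_lt(max(abs(g$coefficients[, "openness"] + 0.3)), 1e-8)
    expect_lt(max(abs(g$fitted - lin$y)), 1e-8)
  }
  # uniform kernel at full bandwidth collapses to OLS
  gu <- fit_gwr(lin, bandwidth = length(lin$y), kernel = "uniform")
  ols <- lm(y ~ ., data = data.frame(y = lin$y, as.data.frame(lin$X)))
  expect_equal(unname(gu$coefficients[1, ]), unname(coef(ols)), tolerance = 1e-8)
})

test_that("GWR tracks a smoothly varying local slope", {
  set.seed(5)
  n <- 200
  coords <- cbind(runif(n, 0, 1000), runif(n, 0, 1000))
  slope_true <- 2 * (coords[, 1] / 1000) - 1 # -1 .. 1 across space
  x1 <- rnorm(n)
  y <- slope_true * x1 + rnorm(n, 0, 0.05)
  d <- tibble::tibble(
    resp = y, ndvi = x1, x = coords[, 1], y = coords[, 2]
  )
  fr <- model_frame(d, response = "resp", factors = "ndvi")
  g <- fit_gwr(fr, bandwidth = 40)
  expect_gte(cor(g$coefficients[, "ndvi"], slope_true), 0.8)
})

test_that("GWRF is deterministic, local, and collapses to the global forest", {
  fr <- tiny_frame()
  n <- length(fr$y)
  g1 <- fit_gwrf(fr, bandwidth = 25, num_trees = 60, min_local = 20, seed = 4)
  g2 <- fit_gwrf(fr, bandwidth = 25, num_trees = 60, min_local = 20, seed = 4)
  expect_identical(g1$fitted, g2$fitted)
  expect_identical(g1$oob, g2$oob)

  expect_error(fit_gwrf(fr, bandwidth = 10, min_local = 30), "minimum local")
  expect_error(fit_gwrf(fr, bandwidth = n + 1), "exceed")

  # global limit: uniform kernel, bandwidth n, shared seed
  rf <- fit_global_rf(fr, num_trees = 80, seed = 7)
  gw <- fit_gwrf(fr, bandwidth = n, kernel = "uniform", num_trees = 80,
    min_local = 20, seed = 7)
  expect_identical(predict(rf), predict(gw))
  Xnew <- fr$X[c(3, 9, 17), ]
  cnew <- fr$coords[c(3, 9, 17), ]
  expect_identical(predict(rf, Xnew), predict(gw, Xnew, cnew))

  # locality: perturbing y outside i's neighborhood leaves i's model alone
  i <- 1
  nb_i <- g1$neighborhoods[[i]]$idx
  outside <- setdiff(seq_len(n), nb_i)[1]
  fr2 <- fr
  fr2$y[outside] <- fr2$y[outside] + 100
  g3 <- fit_gwrf(fr2, bandwidth = 25, num_trees = 60, min_local = 20, seed = 4)
  probe <- fr$X[1:5, ]
  expect_identical(
    predict(g1$forests[[i]], data = as.data.frame(probe), num.threads = 1)$predictions,
    predict(g3$forests[[i]], data = as.data.frame(probe), num.threads = 1)$predictions
  )

  # prediction at a training location routes to that location's own forest
  expect_equal(predict(g1)[i], g1$fitted[i])
})

test_that("the comparison table has the Table-2 shape across scenarios", {
  city <- tiny_city()
  frames <- lapply(c(seasons(), "annual"), function(s) city_model_frame(city, s))
  names(frames) <- c(seasons(), "annual")
  cmp <- compare_models(frames, bandwidth = 25, num_trees = 30,
    evaluation_mode = "in_sample", min_local = 20, seed = 2)
  expect_equal(nrow(cmp), 5 * 3)
  expect_setequal(unique(cmp$scenario), c(seasons(), "annual"))
  expect_setequal(unique(cmp$model), c("rf", "gwr", "gwrf"))
  expect_true(all(cmp$evaluation_mode == "in_sample"))
  expect_true(all(cmp$rmse >= cmp$mae))
})
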