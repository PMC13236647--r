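# Shapley attribution: exactness properties, the analytic linear case,
# Monte-Carlo agreement, and importance rankings.

test_that("exact Shapley reproduces the analytic linear-model values", {
  f <- function(X) 2 * X$a - X$b
  phi <- exact_shapley(f, c(a = 1, b = 1), data.frame(a = 0, b = 0))
  expect_equal(as.numeric(phi), c(2, -1))
  expect_equal(sum(phi), 1) # f(x) - baseline

  # phi = beta * (x - colMeans(background)) for any linear model
  set.seed(12)
  beta <- c(1.5, -2, 0.5, 3)
  bg <- as.data.frame(matrix(rnorm(80), 20, 4))
  names(bg) <- letters[1:4]
  flin <- function(X) as.matrix(X) %*% beta
  x <- c(a = 0.3, b = -1, c = 2, d = 0.1)
  phi <- exact_shapley(flin, x, bg)
  expect_equal(as.numeric(phi), unname(beta * (x - colMeans(bg))), tolerance = 1e-10)
})

test_that("null-player, symmetry and efficiency hold exactly", {
  set.seed(3)
  bg <- data.frame(a = rnorm(15), b = rnorm(15), c = rnorm(15))
  f <- function(X) X$a * X$b # ignores c
  x <- c(a = 1.2, b = 0.7, c = 5)
  phi <- exact_shapley(f, x, bg)
  expect_equal(unname(phi["c"]), 0)

  fsym <- function(X) X$a + X$b + X$a * X$b
  xs <- c(a = 0.4, b = 0.4, c = 1)
  bgs <- data.frame(a = bg$a, b = bg$a, c = bg$c) # identical marginals
  phis <- exact_shapley(fsym, xs, bgs)
  expect_equal(unname(phis["a"]), unname(phis["b"]), tolerance = 1e-12)

  pred <- f(as.data.frame(t(x)))
  expect_equal(sum(phi), pred - attr(phi, "baseline"), tolerance = 1e-12)

  big <- setNames(rep(1, 17), paste0("f", 1:17))
  expect_error(exact_shapley(f, big, bg), "sampled_shapley")
})

test_that("the sampled estimator agrees with exact enumeration within 3 SE", {
  set.seed(21)
  bg <- as.data.frame(matrix(rnorm(100), 20, 5))
  names(bg) <- letters[1:5]
  f <- function(X) X$a * X$b + exp(X$c / 2) - 0.5 * X$d^2 + X$e
  x <- setNames(rnorm(5), letters[1:5])
  ex <- exact_shapley(f, x, bg)
  sm <- sampled_shapley(f, x, bg, n_samples = 400, seed = 2)
  se <- attr(sm, "se")
  expect_true(all(abs(sm - ex) <= 3 * pmax(se, 1e-8)))

  # reproducible under the seed; efficiency holds for the estimate too
  sm2 <- sampled_shapley(f, x, bg, n_samples = 400, seed = 2)
  expect_identical(unclass(sm), unclass(sm2))
  for (ns in c(100, 1000)) {
    s <- sampled_shapley(f, x, bg, n_samples = ns, seed = 5)
    expect_lt(
      abs(sum(s) - (f(as.data.frame(t(x))) - attr(s, "baseline"))), 1e-10
    )
  }
  expect_error(sampled_shapley(f, x, bg, n_samples = 50), "at least 100")
})

test_that("attribution matrices are consistent across methods", {
  set.seed(9)
  X <- as.data.frame(matrix(runif(60), 20, 3))
  names(X) <- c("a", "b", "c")
  f <- function(d) 2 * d$a - d$b + 0.5 * d$a * d$c
  ae <- shapley_attribution(f, X, method = "exact")
  as_ <- shapley_attribution(f, X, method = "sampled", n_samples = 300, seed = 3)
  expect_equal(dim(ae$phi), c(20, 3))
  expect_lt(max(abs(ae$phi - as_$phi)), 0.1)
  # efficiency row-wise for the exact method
  expect_equal(rowSums(ae$phi), ae$predictions - ae$baseline, tolerance = 1e-10)
  td <- tidy(ae)
  expect_equal(nrow(td), 60)
})

test_that("importance ranks follow effect magnitude and cover all factors", {
  set.seed(4)
  X <- as.data.frame(matrix(rnorm(200), 50, 4))
  names(X) <- c("a", "b", "c", "d")
  f <- function(d) 2 * d$a + 1 * d$b # equal scales, A twice B
  att <- shapley_attribution(f, X, method = "exact")
  imp <- global_importance(att)
  expect_equal(imp$factor[1], "a")
  expect_lt(
    which(imp$factor == "a"), which(imp$factor == "b")
  )
  expect_setequal(imp$rank, 1:4)

  f1 <- function(d) 3 * d$c
  imp1 <- global_importance(shapley_attribution(f1, X, method = "exact"))
  expect_equal(imp1$factor[1], "c")
})
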