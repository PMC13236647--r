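# Global random forest, geographically weighted regression, and the
# geographically weighted random forest (GWRF) with adaptive
# neighborhoods, plus the shared evaluation metrics and the three-model
# comparison table.

rf_data <- function(frame) {
  d <- as.data.frame(frame$X)
  d$.y <- frame$y
  d
}

#' Fit a global random forest
#'
#' One forest over all communities — the aspatial benchmark. Fits are
#' deterministic under `seed` (single-threaded).
#'
#' @param frame A [model_frame()].
#' @param num_trees,mtry,min_node_size Forest hyperparameters (defaults
#'   500 trees, p/3 variables per split, minimum leaf size 3).
#' @param seed Integer seed.
#' @return A `global_rf` object.
#' @export
fit_global_rf <- function(frame, num_trees = 500, mtry = NULL,
                          min_node_size = 3, seed = 1) {
  stopifnot(inherits(frame, "model_frame"))
  if (var(frame$y) == 0) {
    warn("Response has zero variance; fitting a degenerate forest.")
  }
  d <- rf_data(frame)
  if (is.null(mtry)) mtry <- max(1L, floor(length(frame$factors) / 3))
  fit <- ranger::ranger(
    dependent.variable.name = ".y", data = d,
    num.trees = num_trees, mtry = mtry, min.node.size = min_node_size,
    seed = seed, num.threads = 1
  )
  structure(
    list(
      fit = fit, frame = frame,
      params = list(num_trees = num_trees, mtry = mtry,
                    min_node_size = min_node_size),
      seed = seed
    ),
    class = "global_rf"
  )
}

#' @export
predict.global_rf <- function(object, new_data = NULL, ...) {
  X <- if (is.null(new_data)) object$frame$X else new_data
  predict(object$fit, data = as.data.frame(X), num.threads = 1)$predictions
}

#' @export
print.global_rf <- function(x, ...) {
  cat(sprintf(
    "<global_rf> %d trees on %d communities, OOB R^2 %.3f\n",
    x$params$num_trees, length(x$frame$y), x$fit$r.squared
  ))
  invisible(x)
}

#' @export
glance.global_rf <- function(x, ...) {
  m <- evaluate_predictions(x$frame$y, x$fit$predictions, "out_of_bag")
  bind_cols(tibble(model = "rf"), m)
}

# Kernel weight profiles over scaled distance t = d / d_max in [0, 1].
gw_kernel <- function(t, kernel) {
  switch(kernel,
    uniform = rep(1, length(t)),
    bisquare = pmax(0, (1 - t^2))^2,
    gaussian = exp(-0.5 * (3 * t)^2),
    abort(sprintf("Unknown kernel '%s'.", kernel))
  )
}

# Adaptive neighborhoods: for each fit location, the `bandwidth` nearest
# observations (ties broken by unit order), the bandwidth distance
# d_max, and kernel weights. Neighbor indices are sorted so that the
# b = n neighborhood reproduces the full frame in original row order.
adaptive_neighborhoods <- function(coords, bandwidth, kernel) {
  n <- nrow(coords)
  d <- cross_dist(coords, coords)
  lapply(seq_len(n), function(i) {
    ord <- order(d[i, ], seq_len(n))
    nb <- sort(ord[seq_len(bandwidth)])
    dmax <- max(d[i, nb])
    t <- if (dmax > 0) d[i, nb] / dmax else rep(0, length(nb))
    list(idx = nb, dist = d[i, nb], dmax = dmax, w = gw_kernel(t, kernel))
  })
}

#' Fit a geographically weighted regression
#'
#' At every community, a kernel-weighted least-squares fit over its
#' adaptive neighborhood (the `bandwidth` nearest communities). With a
#' uniform kernel and `bandwidth = n` every local fit collapses to
#' ordinary least squares. Rank-deficient local designs fall back to a
#' small ridge penalty (1e-8 times the mean weighted diagonal), with a
#' warning.
#'
#' @param frame A [model_frame()].
#' @param bandwidth Adaptive bandwidth: number of nearest neighbors used
#'   in each local fit (default one fifth of the data, at least p + 2).
#' @param kernel `"bisquare"` (default), `"uniform"`, or `"gaussian"`.
#' @return A `gwr_model` with per-location coefficients and in-sample
#'   predictions.
#' @export
fit_gwr <- function(frame, bandwidth = NULL, kernel = "bisquare") {
  stopifnot(inherits(frame, "model_frame"))
  kernel <- match.arg(kernel, c("bisquare", "uniform", "gaussian"))
  n <- length(frame$y)
  p <- length(frame$factors)
  if (is.null(bandwidth)) bandwidth <- max(p + 2, round(n / 5))
  bandwidth <- min(n, max(p + 2, bandwidth))
  nbs <- adaptive_neighborhoods(frame$coords, bandwidth, kernel)
  Xm <- cbind(`(intercept)` = 1, as.matrix(frame$X))
  ridge_warned <- FALSE
  coefs <- matrix(NA_real_, n, ncol(Xm), dimnames = list(NULL, colnames(Xm)))
  for (i in seq_len(n)) {
    nb <- nbs[[i]]
    coefs[i, ] <- local_wls(
      Xm[nb$idx, , drop = FALSE], frame$y[nb$idx], nb$w,
      warn_once = function() {
        if (!ridge_warned) {
          warn("Rank-deficient local design; using a small ridge penalty.")
          ridge_warned <<- TRUE
        }
      }
    )
  }
  fitted <- rowSums(Xm * coefs)
  structure(
    list(
      coefficients = coefs, fitted = fitted, frame = frame,
      bandwidth = bandwidth, kernel = kernel, neighborhoods = nbs
    ),
    class = "gwr_model"
  )
}

# Weighted least squares with ridge fallback.
local_wls <- function(X, y, w, warn_once = function() {}) {
  Xw <- X * w
  XtWX <- crossprod(Xw, X)
  XtWy <- crossprod(Xw, y)
  beta <- tryCatch(
    solve(XtWX, XtWy),
    error = function(e) NULL
  )
  if (is.null(beta) || any(!is.finite(beta))) {
    warn_once()
    lambda <- 1e-8 * mean(diag(XtWX))
    if (!is.finite(lambda) || lambda <= 0) lambda <- 1e-8
    beta <- solve(XtWX + diag(lambda, ncol(X)), XtWy)
  }
  drop(beta)
}

#' @export
predict.gwr_model <- function(object, new_data = NULL, new_coords = NULL, ...) {
  if (is.null(new_data)) return(object$fitted)
  Xm <- cbind(1, as.matrix(new_data[, object$frame$factors]))
  if (is.null(new_coords)) {
    abort("`new_coords` is required to locate the nearest local fit.")
  }
  near <- nearest_index(as.matrix(new_coords), object$frame$coords)
  rowSums(Xm * object$coefficients[near, , drop = FALSE])
}

#' @export
print.gwr_model <- function(x, ...) {
  cat(sprintf(
    "<gwr_model> %d local fits, adaptive bandwidth %d, %s kernel\n",
    nrow(x$coefficients), x$bandwidth, x$kernel
  ))
  invisible(x)
}

#' @export
tidy.gwr_model <- function(x, ...) {
  as_tibble(x$coefficients) |>
    mutate(community_id = x$frame$ids, .before = 1)
}

#' Fit a geographically weighted random forest
#'
#' For every community, a local random forest is trained on its adaptive
#' neighborhood — the `bandwidth` nearest communities — with kernel
#' weights (computed from distance over the bandwidth distance d_max)
#' entering as observation weights. The local model at a community is
#' then responsible for predictions at and around that location. With a
#' uniform kernel and `bandwidth = n`, every local forest sees all data
#' unweighted and the model is exactly the global random forest under
#' the same seed.
#'
#' @inheritParams fit_global_rf
#' @param bandwidth Adaptive bandwidth (neighbor count); must be at
#'   least `min_local` and at most n.
#' @param kernel `"bisquare"` (default), `"uniform"`, or `"gaussian"`.
#' @param min_local Smallest admissible local sample (default 30).
#' @return A `gwrf_model` with per-location forests, neighborhoods,
#'   kernel weights, focal out-of-bag predictions and in-sample
#'   predictions.
#' @export
fit_gwrf <- function(frame, bandwidth = NULL, kernel = "bisquare",
                     num_trees = 500, mtry = NULL, min_node_size = 3,
                     min_local = 30, seed = 1) {
  stopifnot(inherits(frame, "model_frame"))
  kernel <- match.arg(kernel, c("bisquare", "uniform", "gaussian"))
  n <- length(frame$y)
  if (is.null(bandwidth)) bandwidth <- max(min_local, round(n / 5))
  if (bandwidth < min_local) {
    abort(sprintf(
      "`bandwidth` (%d) is below the minimum local sample size (%d).",
      bandwidth, min_local
    ))
  }
  if (bandwidth > n) abort("`bandwidth` cannot exceed the number of communities.")
  if (is.null(mtry)) mtry <- max(1L, floor(length(frame$factors) / 3))
  nbs <- adaptive_neighborhoods(frame$coords, bandwidth, kernel)
  d_all <- rf_data(frame)
  global_case <- kernel == "uniform" && bandwidth == n
  shared <- NULL
  forests <- vector("list", n)
  oob <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    nb <- nbs[[i]]
    if (global_case) {
      if (is.null(shared)) {
        shared <- ranger::ranger(
          dependent.variable.name = ".y", data = d_all,
          num.trees = num_trees, mtry = mtry, min.node.size = min_node_size,
          seed = seed, num.threads = 1
        )
      }
      forests[[i]] <- shared
      oob[i] <- shared$predictions[i]
    } else {
      fit <- ranger::ranger(
        dependent.variable.name = ".y", data = d_all[nb$idx, , drop = FALSE],
        num.trees = num_trees, mtry = mtry, min.node.size = min_node_size,
        case.weights = nb$w, seed = seed, num.threads = 1
      )
      forests[[i]] <- fit
      focal_pos <- match(i, nb$idx)
      oob[i] <- fit$predictions[focal_pos]
    }
  }
  # In-sample prediction at each community from its own local forest.
  fitted <- vapply(seq_len(n), function(i) {
    predict(forests[[i]], data = d_all[i, , drop = FALSE], num.threads = 1)$predictions
  }, numeric(1))
  nan_oob <- !is.finite(oob)
  if (any(nan_oob)) oob[nan_oob] <- fitted[nan_oob] # never out-of-bag: rare
  structure(
    list(
      forests = forests, neighborhoods = nbs, frame = frame,
      bandwidth = bandwidth, kernel = kernel,
      params = list(num_trees = num_trees, mtry = mtry,
                    min_node_size = min_node_size, min_local = min_local),
      seed = seed, oob = oob, fitted = fitted
    ),
    class = "gwrf_model"
  )
}

#' @export
print.gwrf_model <- function(x, ...) {
  cat(sprintf(
    "<gwrf_model> %d local forests (%d trees each), adaptive bandwidth %d, %s kernel\n",
    length(x$forests), x$params$num_trees, x$bandwidth, x$kernel
  ))
  invisible(x)
}

#' @export
glance.gwrf_model <- function(x, ...) {
  bind_cols(
    tibble(model = "gwrf", bandwidth = x$bandwidth, kernel = x$kernel),
    evaluate_predictions(x$frame$y, x$oob, "out_of_bag")
  )
}

#' @export
tidy.gwrf_model <- function(x, ...) {
  tibble(
    community_id = x$frame$ids,
    bandwidth_dist = vapply(x$neighborhoods, `[[`, numeric(1), "dmax"),
    n_neighbors = vapply(x$neighborhoods, function(nb) length(nb$idx), integer(1)),
    oob_prediction = x$oob,
    fitted = x$fitted
  )
}

#' Predict from a geographically weighted random forest
#'
#' Each new point is served by the local forest of the nearest fitted
#' location (no distance blending, so predictions are auditable: one
#' local model per prediction).
#'
#' @param object A [fit_gwrf()] model.
#' @param new_data Data frame with the frame's factor columns; defaults
#'   to the training covariates.
#' @param new_coords Matrix/data frame of planar coordinates aligned
#'   with `new_data`; defaults to the training coordinates.
#' @param ... Unused.
#' @return Numeric predictions.
#' @export
predict.gwrf_model <- function(object, new_data = NULL, new_coords = NULL, ...) {
  if (is.null(new_data)) {
    new_data <- object$frame$X
    new_coords <- object$frame$coords
  }
  if (is.null(new_coords)) {
    abort("`new_coords` is required to route points to local forests.")
  }
  X <- as.data.frame(new_data)[, object$frame$factors, drop = FALSE]
  near <- nearest_index(as.matrix(new_coords), object$frame$coords)
  out <- numeric(nrow(X))
  for (loc in unique(near)) {
    rows <- which(near == loc)
    out[rows] <- predict(
      object$forests[[loc]], data = X[rows, , drop = FALSE], num.threads = 1
    )$predictions
  }
  out
}

#' Regression evaluation metrics
#'
#' `R^2 = 1 - SSE/SST`, `MAE = mean |y - yhat|`,
#' `RMSE = sqrt(mean (y - yhat)^2)`.
#'
#' @param y Observed values (positive variance required).
#' @param yhat Predictions of the same length.
#' @param evaluation_mode Label recorded with the metrics
#'   (`"in_sample"`, `"out_of_bag"`, or `"spatial_cv"`).
#' @return A one-row tibble `r_squared`, `mae`, `rmse`,
#'   `evaluation_mode`.
#' @export
#' @examples
#' evaluate_predictions(c(1, 2, 3), c(1, 2, 4))
evaluate_predictions <- function(y, yhat, evaluation_mode = "in_sample") {
  if (length(y) != length(yhat)) abort("`y` and `yhat` must have equal length.")
  if (length(y) < 2) abort("Need at least two observations.")
  sst <- sum((y - mean(y))^2)
  if (sst == 0) abort("Zero total sum of squares; R^2 is undefined.")
  err <- y - yhat
  tibble(
    r_squared = 1 - sum(err^2) / sst,
    mae = mean(abs(err)),
    rmse = sqrt(mean(err^2)),
    evaluation_mode = evaluation_mode
  )
}

# Spatially blocked folds: k-means clusters of the coordinates.
spatial_folds <- function(coords, k, seed) {
  with_seed(seed, {
    km <- kmeans(coords, centers = k, nstart = 5)
    km$cluster
  })
}

#' Compare RF, GWR and GWRF across scenarios
#'
#' Fits the three models on each supplied scenario frame and scores them
#' with a common protocol: spatially blocked k-fold cross-validation
#' (default), pure in-sample fit, or out-of-bag/holdout-style
#' predictions (forest OOB; leave-self-out local fits for GWR).
#'
#' @param frames A named list of [model_frame()]s (e.g. the four seasons
#'   plus `"annual"`), or a single frame.
#' @param bandwidth Adaptive bandwidth used by GWR and GWRF (default one
#'   fifth of each frame).
#' @param kernel Kernel for the geographically weighted models.
#' @param num_trees,min_node_size Forest hyperparameters.
#' @param evaluation_mode `"spatial_cv"`, `"in_sample"`, or
#'   `"out_of_bag"`.
#' @param folds Number of spatial folds for cross-validation.
#' @param min_local Minimum local sample for GWRF.
#' @param seed Integer master seed.
#' @return A tibble: `scenario`, `model`, `r_squared`, `mae`, `rmse`,
#'   `evaluation_mode`.
#' @export
compare_models <- function(frames, bandwidth = NULL, kernel = "bisquare",
                           num_trees = 500, min_node_size = 3,
                           evaluation_mode = "spatial_cv", folds = 5,
                           min_local = 30, seed = 1) {
  if (inherits(frames, "model_frame")) frames <- list(scenario = frames)
  evaluation_mode <- match.arg(evaluation_mode,
    c("spatial_cv", "in_sample", "out_of_bag"))
  rows <- imap(frames, function(frame, label) {
    n <- length(frame$y)
    bw <- min(n, bandwidth %||% max(min_local, round(n / 5)))
    preds <- model_predictions(
      frame, bw, kernel, num_trees, min_node_size, evaluation_mode,
      folds, min_local, derive_seed(seed, label)
    )
    bind_rows(lapply(names(preds), function(m) {
      bind_cols(
        tibble(scenario = label, model = m),
        evaluate_predictions(frame$y, preds[[m]], evaluation_mode)
      )
    }))
  })
  bind_rows(rows)
}

# Predictions of the three models under one evaluation protocol.
model_predictions <- function(frame, bw, kernel, num_trees, min_node_size,
                              mode, folds, min_local, seed) {
  n <- length(frame$y)
  if (mode == "spatial_cv") {
    fold <- spatial_folds(frame$coords, folds, seed)
    out <- list(
      rf = rep(NA_real_, n), gwr = rep(NA_real_, n), gwrf = rep(NA_real_, n)
    )
    for (f in sort(unique(fold))) {
      test <- which(fold == f)
      train <- which(fold != f)
      tr <- frame_subset(frame, train)
      rf <- fit_global_rf(tr, num_trees = num_trees,
        min_node_size = min_node_size, seed = seed)
      out$rf[test] <- predict(rf, frame$X[test, , drop = FALSE])
      bw_f <- min(length(train), bw)
      gwr <- fit_gwr(tr, bandwidth = bw_f, kernel = kernel)
      out$gwr[test] <- predict(gwr, frame$X[test, , drop = FALSE],
        frame$coords[test, , drop = FALSE])
      gwrf <- fit_gwrf(tr, bandwidth = bw_f, kernel = kernel,
        num_trees = num_trees, min_node_size = min_node_size,
        min_local = min(min_local, bw_f), seed = seed)
      out$gwrf[test] <- predict(gwrf, frame$X[test, , drop = FALSE],
        frame$coords[test, , drop = FALSE])
    }
    out
  } else {
    rf <- fit_global_rf(frame, num_trees = num_trees,
      min_node_size = min_node_size, seed = seed)
    gwr <- fit_gwr(frame, bandwidth = bw, kernel = kernel)
    gwrf <- fit_gwrf(frame, bandwidth = bw, kernel = kernel,
      num_trees = num_trees, min_node_size = min_node_size,
      min_local = min(min_local, bw), seed = seed)
    if (mode == "in_sample") {
      list(
        rf = predict(rf), gwr = gwr$fitted, gwrf = gwrf$fitted
      )
    } else {
      list(
        rf = rf$fit$predictions,
        gwr = gwr_loo_fitted(gwr),
        gwrf = gwrf$oob
      )
    }
  }
}

# Leave-self-out fitted values for GWR: refit each local model with the
# focal observation's weight set to zero.
gwr_loo_fitted <- function(gwr) {
  frame <- gwr$frame
  Xm <- cbind(1, as.matrix(frame$X))
  vapply(seq_along(frame$y), function(i) {
    nb <- gwr$neighborhoods[[i]]
    w <- nb$w
    w[nb$idx == i] <- 0
    beta <- local_wls(Xm[nb$idx, , drop = FALSE], frame$y[nb$idx], w)
    sum(Xm[i, ] * beta)
  }, numeric(1))
}

#' Select the GWRF bandwidth by out-of-bag error
#'
#' Grid search over candidate neighbor counts, minimizing the RMSE of
#' the focal out-of-bag predictions.
#'
#' @inheritParams fit_gwrf
#' @param candidates Integer vector of neighbor counts to try.
#' @return A list: `bandwidth` (the winner) and `profile` (tibble of
#'   candidate x RMSE).
#' @export
select_bandwidth <- function(frame, candidates, kernel = "bisquare",
                             num_trees = 200, min_local = 30, seed = 1) {
  stopifnot(inherits(frame, "model_frame"))
  profile <- bind_rows(lapply(candidates, function(b) {
    fit <- fit_gwrf(frame, bandwidth = b, kernel = kernel,
      num_trees = num_trees, min_local = min_local, seed = seed)
    tibble(bandwidth = b, oob_rmse = sqrt(mean((frame$y - fit$oob)^2)))
  }))
  list(
    bandwidth = profile$bandwidth[which.min(profile$oob_rmse)],
    profile = profile
  )
}
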