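# Interpretation of fitted models: partial-dependence curves with
# threshold detection, per-community dominant factors from local Shapley
# values, and signed local effect surfaces.

#' Partial-dependence curve of one factor
#'
#' `PDP(g)` is the mean model output over the observations with the
#' factor set to grid value `g`. The grid is the factor's quantile grid
#' (so it stays within the observed range); the dispersion band is the
#' across-observation standard deviation of the response at each grid
#' point — a spread measure, not a confidence interval.
#'
#' @param model_fn Prediction function over factor data frames.
#' @param data Data frame of observations (factor columns).
#' @param factor Factor name.
#' @param grid_size Number of quantile grid points (default 15).
#' @param grid Optional explicit grid, overriding `grid_size`.
#' @return A `pdp_curve` tibble: `factor`, `grid`, `estimate`, `band`.
#' @export
partial_dependence <- function(model_fn, data, factor, grid_size = 15,
                               grid = NULL) {
  data <- as.data.frame(data)
  if (!factor %in% names(data)) abort(sprintf("Factor '%s' not in data.", factor))
  v <- data[[factor]]
  if (is.null(grid)) {
    if (length(unique(v)) == 1) {
      warn(sprintf("Factor '%s' is constant; returning a single-point curve.", factor))
      grid <- v[1]
    } else {
      grid <- unique(quantile(v, probs = seq(0, 1, length.out = grid_size),
        names = FALSE, type = 7))
    }
  }
  m <- nrow(data)
  stacked <- data[rep(seq_len(m), times = length(grid)), , drop = FALSE]
  stacked[[factor]] <- rep(grid, each = m)
  preds <- model_fn(stacked)
  pm <- matrix(preds, nrow = m)
  out <- tibble(
    factor = factor,
    grid = grid,
    estimate = colMeans(pm),
    band = apply(pm, 2, sd)
  )
  class(out) <- c("pdp_curve", class(out))
  out
}

#' Locate the turning point of a partial-dependence curve
#'
#' Finds where the curve's slope changes sign — for a V-shaped
#' (negative-then-positive) relationship this is the interior minimum,
#' for an inverted-V the interior maximum. The curve is lightly smoothed
#' with a centered moving average before the extremum is taken, to keep
#' single-step forest jitter from masquerading as a turning point.
#'
#' @param curve A [partial_dependence()] result.
#' @param direction `"auto"` (default; pick the more pronounced of
#'   minimum/maximum), `"min"`, or `"max"`.
#' @param smooth_window Odd window length of the moving average
#'   (default 3; 1 disables smoothing).
#' @return The grid value of the turning point, or `NA` if the curve is
#'   monotone to within smoothing.
#' @export
find_turning_point <- function(curve, direction = c("auto", "min", "max"),
                               smooth_window = 3) {
  direction <- match.arg(direction)
  g <- curve$grid
  yv <- curve$estimate
  k <- length(g)
  if (k < 3) return(NA_real_)
  if (smooth_window > 1) {
    half <- floor(smooth_window / 2)
    yv <- vapply(seq_len(k), function(i) {
      mean(curve$estimate[max(1, i - half):min(k, i + half)])
    }, numeric(1))
  }
  i_min <- which.min(yv)
  i_max <- which.max(yv)
  depth_v <- min(yv[1], yv[k]) - yv[i_min] # how pronounced a V is
  depth_peak <- yv[i_max] - max(yv[1], yv[k]) # how pronounced a peak is
  pick <- switch(direction,
    min = i_min,
    max = i_max,
    auto = if (depth_v >= depth_peak) i_min else i_max
  )
  interior_ok <- switch(direction,
    min = depth_v > 0, max = depth_peak > 0,
    auto = max(depth_v, depth_peak) > 0
  )
  if (!interior_ok) return(NA_real_)
  g[pick]
}

# Prediction closure of one GWRF local forest.
local_forest_fn <- function(gwrf, i) {
  force(i)
  function(X) {
    predict(gwrf$forests[[i]], data = as.data.frame(X), num.threads = 1)$predictions
  }
}

#' Per-community dominant factors from local Shapley values
#'
#' For every community, Shapley values are computed under its *local*
#' forest, with both the explained observations and the background drawn
#' from the community's adaptive neighborhood. The dominant factor is
#' the one with the largest mean absolute Shapley value (ties broken by
#' configured factor order). Shares of communities per dominant factor
#' are tabulated alongside.
#'
#' @param gwrf A [fit_gwrf()] model.
#' @param n_samples Shapley permutation samples per community. The
#'   default (32) is sized for the argmax decision, whose margins are
#'   large; raise it if the per-factor values themselves are of
#'   interest.
#' @param max_obs Neighborhood observations explained per community
#'   (subsampled deterministically; the focal community is always
#'   included).
#' @param max_background Background rows per community.
#' @param seed Integer seed.
#' @return A `dominant_factor_map`: `communities` tibble
#'   (`community_id`, `x`, `y`, `dominant_factor`, `mean_abs_phi`) and
#'   `shares` tibble (`factor`, `n_communities`, `share_pct`).
#' @export
local_dominant_factors <- function(gwrf, n_samples = 32, max_obs = 6,
                                   max_background = 12, seed = 1) {
  stopifnot(inherits(gwrf, "gwrf_model"))
  frame <- gwrf$frame
  n <- length(frame$y)
  p <- length(frame$factors)
  dominant <- character(n)
  strength <- numeric(n)
  for (i in seq_len(n)) {
    nb <- gwrf$neighborhoods[[i]]$idx
    obs <- nb
    bg <- nb
    si <- derive_seed(seed, paste0("dom", i))
    res <- with_seed(si, {
      if (length(obs) > max_obs) {
        # always include the focal community itself
        obs <- union(i, sample(nb, max_obs - 1L))
      }
      if (length(bg) > max_background) bg <- sample(nb, max_background)
      shapley_permutation_matrix(
        local_forest_fn(gwrf, i),
        as.matrix(frame$X[obs, , drop = FALSE]),
        frame$X[bg, , drop = FALSE],
        n_samples
      )
    })
    imp <- colMeans(abs(res$phi))
    j <- which.max(imp) # ties: first factor in configured order
    dominant[i] <- frame$factors[j]
    strength[i] <- imp[j]
  }
  communities <- tibble(
    community_id = frame$ids,
    x = frame$coords[, 1], y = frame$coords[, 2],
    dominant_factor = dominant,
    mean_abs_phi = strength
  )
  shares <- communities |>
    group_by(factor = .data$dominant_factor) |>
    summarise(n_communities = n(), .groups = "drop") |>
    mutate(share_pct = 100 * .data$n_communities / sum(.data$n_communities)) |>
    arrange(desc(.data$share_pct))
  structure(
    list(communities = communities, shares = shares, seed = seed),
    class = "dominant_factor_map"
  )
}

#' @export
print.dominant_factor_map <- function(x, ...) {
  cat(sprintf("<dominant_factor_map> %d communities\n", nrow(x$communities)))
  print(x$shares)
  invisible(x)
}

#' @export
tidy.dominant_factor_map <- function(x, ...) x$shares

#' Signed local association of a factor with the response
#'
#' For each community, a local partial-dependence curve of the factor is
#' evaluated under the community's local forest, averaging over its
#' neighborhood observations and spanning the neighborhood's factor
#' range; the least-squares slope of that curve is the signed local
#' association exported for mapping. Communities whose neighborhood has
#' (near-)constant factor values get `NA` and are flagged.
#'
#' @param gwrf A [fit_gwrf()] model.
#' @param factor Factor name.
#' @param grid_size Grid points of the local curve (default 7).
#' @return A tibble: `community_id`, `x`, `y`, `slope`, `sign`.
#' @export
local_effect_surface <- function(gwrf, factor, grid_size = 7) {
  stopifnot(inherits(gwrf, "gwrf_model"))
  frame <- gwrf$frame
  if (!factor %in% frame$factors) abort(sprintf("Unknown factor '%s'.", factor))
  n <- length(frame$y)
  slope <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    nb <- gwrf$neighborhoods[[i]]$idx
    v <- frame$X[[factor]][nb]
    if (diff(range(v)) < 1e-12) next # flagged: no local variation
    grid <- unique(quantile(v, probs = seq(0, 1, length.out = grid_size),
      names = FALSE))
    curve <- partial_dependence(
      local_forest_fn(gwrf, i), frame$X[nb, , drop = FALSE], factor,
      grid = grid
    )
    slope[i] <- coef(lm(curve$estimate ~ curve$grid))[2]
  }
  if (anyNA(slope)) {
    warn(sprintf(
      "%d community(ies) have no local variation in '%s'; slope set to NA.",
      sum(is.na(slope)), factor
    ))
  }
  tibble(
    community_id = frame$ids,
    x = frame$coords[, 1], y = frame$coords[, 2],
    slope = slope,
    sign = sign(slope)
  )
}
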