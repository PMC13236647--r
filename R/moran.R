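# Global and local Moran's I with permutation inference, over simple
# k-nearest-neighbor or rook spatial weights.

#' Build spatial weights
#'
#' `"knn"` connects each unit to its `k` nearest neighbors by Euclidean
#' distance on planar coordinates (ties, including exact duplicate
#' coordinates, broken by unit order, with a warning for duplicates).
#' `"rook"` connects orthogonally adjacent points on an integer-spaced
#' lattice (intended for raster fixtures). Rows can be standardized to
#' sum to 1; isolated units are flagged.
#'
#' @param coords Two-column matrix or data frame of planar coordinates.
#' @param scheme `"knn"` or `"rook"`.
#' @param k Neighbor count for kNN (default 8; must be < n).
#' @param row_standardize Standardize rows to sum to 1 (default `TRUE`)?
#' @return A `spatial_weights` object: `neighbors` (list of integer
#'   vectors), `weights` (list of numerics), `n`, `scheme`,
#'   `row_standardized`.
#' @export
build_weights <- function(coords, scheme = c("knn", "rook"), k = 8,
                          row_standardize = TRUE) {
  scheme <- match.arg(scheme)
  coords <- as.matrix(as.data.frame(coords))
  n <- nrow(coords)
  if (n < 3) abort("Need at least 3 units.")
  if (scheme == "knn") {
    check_number(k, "k", positive = TRUE, integerish = TRUE)
    if (k >= n) abort("`k` must be smaller than the number of units.")
    if (anyDuplicated(coords) > 0) {
      warn("Duplicate coordinates; neighbor ties broken by unit order.")
    }
    d <- cross_dist(coords, coords)
    diag(d) <- Inf
    nbs <- lapply(seq_len(n), function(i) {
      # stable order: distance, then unit id
      ord <- order(d[i, ], seq_len(n))
      ord[seq_len(k)]
    })
  } else {
    gaps <- c(diff(sort(unique(coords[, 1]))), diff(sort(unique(coords[, 2]))))
    gaps <- gaps[gaps > 0]
    step <- if (length(gaps) == 0) 1 else min(gaps) # lattice spacing
    d <- cross_dist(coords, coords)
    nbs <- lapply(seq_len(n), function(i) {
      which(abs(d[i, ] - step) < 1e-9 * max(step, 1))
    })
  }
  wts <- lapply(nbs, function(nb) rep(1, length(nb)))
  if (row_standardize) {
    isolated <- vapply(nbs, length, integer(1)) == 0
    if (any(isolated)) {
      warn(sprintf("%d isolated unit(s) have empty weight rows.", sum(isolated)))
    }
    wts <- lapply(wts, function(w) if (length(w) > 0) w / sum(w) else w)
  }
  structure(
    list(
      neighbors = nbs, weights = wts, n = n, scheme = scheme,
      row_standardized = row_standardize
    ),
    class = "spatial_weights"
  )
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat(sprintf(
    "<spatial_weights> n = %d, scheme = %s, row standardized = %s\n",
    x$n, x$scheme, x$row_standardized
  ))
  invisible(x)
}

# Triplet form (i, j, w) of a spatial_weights object.
weights_triplet <- function(W) {
  ii <- rep(seq_len(W$n), vapply(W$neighbors, length, integer(1)))
  jj <- unlist(W$neighbors)
  ww <- unlist(W$weights)
  list(i = ii, j = jj, w = ww, s0 = sum(ww))
}

# Spatially lagged values.
spatial_lag <- function(W, z) {
  vapply(seq_len(W$n), function(i) {
    nb <- W$neighbors[[i]]
    if (length(nb) == 0) 0 else sum(W$weights[[i]] * z[nb])
  }, numeric(1))
}

#' Global Moran's I with permutation inference
#'
#' `I = (n / S0) * sum_ij w_ij z_i z_j / sum_i z_i^2`, with z the
#' deviations from the mean. The permutation p-value is two-sided around
#' the null expectation `-1/(n-1)`:
#' `p = (#permutations at least as extreme + 1) / (n_perm + 1)`.
#'
#' @param values Numeric vector with positive variance.
#' @param W A [build_weights()] result.
#' @param n_perm Number of random relabelings (default 999).
#' @param seed Integer seed for the permutations.
#' @return A `moran_result`: `I`, `expected` (-1/(n-1)), `p_perm`,
#'   `n_perm`, `seed`, `perm_values`.
#' @export
global_morans_i <- function(values, W, n_perm = 999, seed = 1) {
  stopifnot(inherits(W, "spatial_weights"))
  if (length(values) != W$n) abort("`values` length must match the weights.")
  if (var(values) == 0) abort("Moran's I is undefined for zero-variance values.")
  tri <- weights_triplet(W)
  n <- W$n
  moran_stat <- function(z) {
    (n / tri$s0) * sum(tri$w * z[tri$i] * z[tri$j]) / sum(z^2)
  }
  z <- values - mean(values)
  I <- moran_stat(z)
  e0 <- -1 / (n - 1)
  perms <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) moran_stat(z[sample.int(n)]), numeric(1))
  })
  p <- (sum(abs(perms - e0) >= abs(I - e0) - 1e-12) + 1) / (n_perm + 1)
  structure(
    list(
      I = I, expected = e0, p_perm = p, n_perm = n_perm, seed = seed,
      perm_values = perms
    ),
    class = "moran_result"
  )
}

#' @export
print.moran_result <- function(x, ...) {
  cat(sprintf(
    "Global Moran's I = %.4f (expected %.4f), permutation p = %.4g (%d perms)\n",
    x$I, x$expected, x$p_perm, x$n_perm
  ))
  invisible(x)
}

#' @export
glance.moran_result <- function(x, ...) {
  tibble(I = x$I, expected = x$expected, p_perm = x$p_perm, n_perm = x$n_perm)
}

#' Local Moran's I (LISA) with conditional permutation
#'
#' `I_i = z_i * lag_i / m2` with `m2 = sum(z^2)/n`. Each unit's p-value
#' comes from conditional permutation: holding `z_i` fixed, its neighbor
#' values are drawn from the remaining units. Units with `p <= alpha`
#' are classed by quadrant of `(z_i, lag_i)`: HH, LL, HL (high value,
#' low neighbors), or LH; all others are `"ns"`.
#'
#' @inheritParams global_morans_i
#' @param alpha Significance gate for cluster classes (default 0.05).
#' @return A `lisa_result` tibble: `unit`, `local_i`, `p_perm`, `class`.
#' @export
local_morans_i <- function(values, W, alpha = 0.05, n_perm = 999, seed = 1) {
  stopifnot(inherits(W, "spatial_weights"))
  if (length(values) != W$n) abort("`values` length must match the weights.")
  if (var(values) == 0) abort("Local Moran's I is undefined for zero variance.")
  n <- W$n
  z <- values - mean(values)
  m2 <- sum(z^2) / n
  lag <- spatial_lag(W, z)
  li <- z * lag / m2
  p <- with_seed(seed, {
    vapply(seq_len(n), function(i) {
      nb <- W$neighbors[[i]]
      if (length(nb) == 0) return(NA_real_)
      wv <- W$weights[[i]]
      pool <- z[-i]
      sims <- vapply(seq_len(n_perm), function(b) {
        zs <- pool[sample.int(n - 1, length(nb))]
        z[i] * sum(wv * zs) / m2
      }, numeric(1))
      (sum(abs(sims) >= abs(li[i]) - 1e-12) + 1) / (n_perm + 1)
    }, numeric(1))
  })
  cls <- rep("ns", n)
  sig <- !is.na(p) & p <= alpha
  cls[sig & z > 0 & lag > 0] <- "HH"
  cls[sig & z < 0 & lag < 0] <- "LL"
  cls[sig & z > 0 & lag <= 0] <- "HL"
  cls[sig & z < 0 & lag >= 0] <- "LH"
  out <- tibble(unit = seq_len(n), local_i = li, p_perm = p, class = cls)
  class(out) <- c("lisa_result", class(out))
  attr(out, "alpha") <- alpha
  attr(out, "n_perm") <- n_perm
  out
}

#' @export
tidy.lisa_result <- function(x, ...) as_tibble(x)

#' Per-class LISA counts
#'
#' @param x A [local_morans_i()] result.
#' @return A tibble `class`, `n_units`, `share` (fractions of units).
#' @export
lisa_class_counts <- function(x) {
  stopifnot(inherits(x, "lisa_result"))
  x |>
    group_by(class = .data$class) |>
    summarise(n_units = n(), .groups = "drop") |>
    mutate(share = .data$n_units / sum(.data$n_units))
}
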