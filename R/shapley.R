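# Shapley-value attribution with an interventional value function:
# v(S) is the mean model output over a background sample in which the
# factors outside S are replaced by background values. Exact enumeration
# for small factor sets; a permutation-sampling estimator otherwise.

# Normalize inputs: x as a named numeric vector, background as a data
# frame restricted to the factor set.
shapley_inputs <- function(x, background, factors) {
  if (is.data.frame(x)) x <- unlist(x[1, , drop = TRUE])
  if (is.null(factors)) factors <- names(x)
  if (is.null(factors) || any(!nzchar(factors))) {
    abort("`factors` (or named `x`) is required.")
  }
  background <- as.data.frame(background)[, factors, drop = FALSE]
  if (nrow(background) == 0) abort("`background` must be non-empty.")
  list(x = x[factors], background = background, factors = factors)
}

#' Exact Shapley values by subset enumeration
#'
#' Computes the Shapley value of every factor for one observation:
#' `phi_i = sum_S |S|! (p-|S|-1)! / p! * (v(S u i) - v(S))` with the
#' interventional value function `v(S)` = mean model output over the
#' background rows with the factors in S set to the observation's
#' values. Exact enumeration visits all `2^p` subsets and is limited to
#' p <= 16 factors; beyond that use [sampled_shapley()].
#'
#' Satisfies efficiency (`sum(phi) = f(x) - baseline`), the null-player
#' property, and symmetry exactly (to numerical tolerance).
#'
#' @param model_fn Prediction function: takes a data frame of factor
#'   columns, returns a numeric vector.
#' @param x One observation: named numeric vector or one-row data frame.
#' @param background Data frame of reference observations defining v(S).
#' @param factors Factor names (default: names of `x`).
#' @return Named numeric vector of Shapley values, with attributes
#'   `baseline` (v of the empty set) and `prediction` (f(x)).
#' @export
#' @examples
#' f <- function(X) 2 * X$a - X$b
#' exact_shapley(f, c(a = 1, b = 1), data.frame(a = 0, b = 0))
exact_shapley <- function(model_fn, x, background, factors = NULL) {
  p_guess <- length(factors %||% names(x))
  if (p_guess > 16) {
    abort("Exact enumeration is limited to 16 factors; use sampled_shapley().")
  }
  inp <- shapley_inputs(x, background, factors)
  p <- length(inp$factors)
  B <- nrow(inp$background)
  n_masks <- bitwShiftL(1L, p)
  if (as.numeric(n_masks) * B > 2e6) {
    abort("Subset enumeration too large; shrink the background or use sampled_shapley().")
  }
  # One stacked prediction call over all masks.
  eval_rows <- vector("list", n_masks)
  for (m in seq_len(n_masks) - 1L) {
    bg <- inp$background
    for (j in seq_len(p)) {
      if (bitwAnd(m, bitwShiftL(1L, j - 1L)) != 0L) bg[[j]] <- inp$x[[j]]
    }
    eval_rows[[m + 1L]] <- bg
  }
  preds <- model_fn(do.call(rbind, eval_rows))
  v <- vapply(seq_len(n_masks), function(k) {
    mean(preds[((k - 1) * B + 1):(k * B)])
  }, numeric(1))
  sizes <- vapply(seq_len(n_masks) - 1L, function(m) sum(bitwAnd(m, bitwShiftL(1L, 0:(p - 1))) != 0L), numeric(1))
  wts <- factorial(0:(p - 1)) * factorial(p - 1 - (0:(p - 1))) / factorial(p)
  phi <- setNames(numeric(p), inp$factors)
  for (j in seq_len(p)) {
    bit <- bitwShiftL(1L, j - 1L)
    without <- which(bitwAnd(seq_len(n_masks) - 1L, bit) == 0L)
    s <- sizes[without]
    phi[j] <- sum(wts[s + 1] * (v[without + bit] - v[without]))
  }
  structure(phi, baseline = v[1], prediction = v[n_masks])
}

#' Monte-Carlo Shapley values by permutation sampling
#'
#' Unbiased permutation-sampling estimator of the same quantity as
#' [exact_shapley()]: factors are added in `n_samples` random orders and
#' marginal contributions averaged. Because contributions telescope
#' within each permutation, the efficiency identity
#' `sum(phi) = f(x) - baseline` holds for the estimate as well.
#'
#' @inheritParams exact_shapley
#' @param n_samples Number of sampled permutations (>= 100).
#' @param seed Integer seed.
#' @return As [exact_shapley()], with an extra attribute `se` (per-factor
#'   Monte-Carlo standard errors).
#' @export
sampled_shapley <- function(model_fn, x, background, factors = NULL,
                            n_samples = 200, seed = 1) {
  if (n_samples < 100) abort("`n_samples` must be at least 100.")
  inp <- shapley_inputs(x, background, factors)
  res <- with_seed(seed, {
    shapley_permutation_matrix(
      model_fn, matrix(inp$x, nrow = 1, dimnames = list(NULL, inp$factors)),
      inp$background, n_samples
    )
  })
  phi <- setNames(res$phi[1, ], inp$factors)
  structure(
    phi,
    baseline = res$baseline, prediction = res$prediction[1],
    se = setNames(res$se[1, ], inp$factors)
  )
}

# Shared-permutation batch estimator: phi for every row of X at once.
# Callers manage the RNG state. Returns per-observation phi, Monte-Carlo
# standard errors, baseline and predictions.
shapley_permutation_matrix <- function(model_fn, X, background, n_samples) {
  X <- as.matrix(X)
  p <- ncol(X)
  m <- nrow(X)
  factors <- colnames(X)
  bg <- as.matrix(background[, factors, drop = FALSE])
  B <- nrow(bg)
  phi_sum <- matrix(0, m, p, dimnames = list(NULL, factors))
  phi_sq <- matrix(0, m, p)
  baseline <- NULL
  pred_full <- NULL
  for (s in seq_len(n_samples)) {
    ord <- sample.int(p)
    # Build the p+1 prefix masks, stacked as (prefix, obs, background).
    rows <- matrix(0, (p + 1L) * m * B, p, dimnames = list(NULL, factors))
    for (k in 0:p) {
      mask <- ord[seq_len(k)]
      block <- bg[rep(seq_len(B), times = m), , drop = FALSE]
      if (k > 0) {
        xs <- X[rep(seq_len(m), each = B), mask, drop = FALSE]
        block[, mask] <- xs
      }
      rows[(k * m * B + 1):((k + 1) * m * B), ] <- block
    }
    preds <- model_fn(as.data.frame(rows))
    # v[k+1, o] = mean over background of prefix k for observation o
    v <- array(preds, dim = c(B, m, p + 1L))
    v <- apply(v, c(2, 3), mean) # m x (p+1)
    contrib <- v[, -1, drop = FALSE] - v[, -(p + 1L), drop = FALSE]
    # contribution k belongs to factor ord[k]
    phi_sum[, ord] <- phi_sum[, ord] + contrib
    phi_sq[, ord] <- phi_sq[, ord] + contrib^2
    if (is.null(baseline)) baseline <- mean(v[, 1])
    pred_full <- v[, p + 1L]
  }
  phi <- phi_sum / n_samples
  se <- sqrt(pmax(phi_sq / n_samples - phi^2, 0) / n_samples)
  list(phi = phi, se = se, baseline = baseline, prediction = pred_full)
}

#' Shapley attribution for a set of observations
#'
#' Computes the observation x factor matrix of Shapley values for a
#' fitted model over a background sample.
#'
#' @param model_fn Prediction function over factor data frames.
#' @param X Data frame of observations to explain.
#' @param background Background data frame (defaults to `X`).
#' @param method `"sampled"` (default) or `"exact"` (p <= 16 only).
#' @param n_samples Permutations for the sampled method.
#' @param max_background Background rows are subsampled to this size for
#'   tractability (deterministic under `seed`).
#' @param seed Integer seed.
#' @return A `shapley_attribution`: `phi` (matrix), `baseline`,
#'   `predictions`, `factors`, `method`, `n_samples`, `seed`.
#' @export
shapley_attribution <- function(model_fn, X, background = X,
                                method = c("sampled", "exact"),
                                n_samples = 128, max_background = 50,
                                seed = 1) {
  method <- match.arg(method)
  X <- as.data.frame(X)
  factors <- colnames(X)
  background <- as.data.frame(background)[, factors, drop = FALSE]
  if (nrow(background) > max_background) {
    background <- with_seed(derive_seed(seed, "bg"), {
      background[sample.int(nrow(background), max_background), , drop = FALSE]
    })
  }
  if (method == "exact") {
    phis <- lapply(seq_len(nrow(X)), function(i) {
      exact_shapley(model_fn, unlist(X[i, ]), background, factors)
    })
    phi <- do.call(rbind, lapply(phis, as.numeric))
    colnames(phi) <- factors
    baseline <- attr(phis[[1]], "baseline")
    preds <- vapply(phis, attr, numeric(1), "prediction")
  } else {
    res <- with_seed(seed, {
      shapley_permutation_matrix(model_fn, as.matrix(X), background, n_samples)
    })
    phi <- res$phi
    baseline <- res$baseline
    preds <- res$prediction
  }
  structure(
    list(
      phi = phi, baseline = baseline, predictions = preds,
      factors = factors, method = method, n_samples = n_samples, seed = seed
    ),
    class = "shapley_attribution"
  )
}

#' @export
print.shapley_attribution <- function(x, ...) {
  cat(sprintf(
    "<shapley_attribution> %d observations x %d factors (%s), baseline %.4f\n",
    nrow(x$phi), length(x$factors), x$method, x$baseline
  ))
  invisible(x)
}

#' @export
tidy.shapley_attribution <- function(x, ...) {
  as_tibble(x$phi) |>
    mutate(observation = row_number(), .before = 1) |>
    tidyr::pivot_longer(-"observation", names_to = "factor", values_to = "phi")
}

#' Global factor importance from Shapley values
#'
#' Mean absolute Shapley value per factor, ranked in descending order.
#' Ties are broken by factor order in the attribution (the configured
#' factor order).
#'
#' @param attr A [shapley_attribution()].
#' @return An `importance_ranking` tibble: `factor`, `mean_abs_phi`,
#'   `rank`.
#' @export
global_importance <- function(attr) {
  stopifnot(inherits(attr, "shapley_attribution"))
  if (nrow(attr$phi) == 0) abort("Empty attribution.")
  imp <- colMeans(abs(attr$phi))
  ord <- order(-imp, seq_along(imp))
  out <- tibble(
    factor = attr$factors,
    mean_abs_phi = as.numeric(imp),
    rank = integer(length(imp))
  )
  out$rank[ord] <- seq_along(imp)
  out <- arrange(out, .data$rank)
  class(out) <- c("importance_ranking", class(out))
  out
}
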