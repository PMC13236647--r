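# Internal helpers shared across modules.

# Derive a reproducible child seed from a master seed and a stage label.
# Keeps results below 2^31 so they are valid R integer seeds.
derive_seed <- function(master_seed, label) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1)
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((abs(master_seed) * 48271 + h * 16807) %% 2147483629L)
}

# Evaluate an expression under a local RNG state so callers' streams are
# never disturbed.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

check_number <- function(x, name, positive = FALSE, integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be positive (got %g).", name, x))
  }
  if (integerish && abs(x - round(x)) > 1e-8) {
    abort(sprintf("`%s` must be a whole number (got %g).", name, x))
  }
  invisible(x)
}

check_season <- function(season) {
  if (!is.character(season) || length(season) != 1 || !season %in% SEASONS) {
    abort(sprintf(
      "`season` must be one of %s.",
      paste0("'", SEASONS, "'", collapse = ", ")
    ))
  }
  season
}

# Pairwise Euclidean distances between two coordinate matrices.
cross_dist <- function(a, b) {
  a <- as.matrix(a)
  b <- as.matrix(b)
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

# For each row of `pts`, index of the nearest row of `centers`.
nearest_index <- function(pts, centers) {
  max.col(-cross_dist(pts, centers), ties.method = "first")
}
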