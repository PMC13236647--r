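# The community x factor modelling frame shared by all models.

#' Build a modelling frame
#'
#' Bundles the response, the covariate matrix and the planar coordinates
#' of the communities for one modelling scenario (a season or the pooled
#' annual data). The frame refuses missing covariate cells: communities
#' with incomplete covariates must be fixed or dropped upstream.
#'
#' @param data Data frame containing the response, factor and coordinate
#'   columns, one row per community.
#' @param response Name of the response column (the emotion index).
#' @param factors Character vector of covariate columns (default: the 14
#'   canonical factors present in `data`).
#' @param coords Names of the x/y coordinate columns.
#' @param season Scenario label stored with the frame.
#' @param id Name of the community id column, if present.
#' @return A `model_frame` object.
#' @export
model_frame <- function(data, response = "index", factors = NULL,
                        coords = c("x", "y"), season = NA_character_,
                        id = "community_id") {
  data <- as_tibble(data)
  if (is.null(factors)) factors <- intersect(FACTOR_NAMES, names(data))
  missing_cols <- setdiff(c(response, factors, coords), names(data))
  if (length(missing_cols) > 0) {
    abort(sprintf("Missing columns: %s.", paste(missing_cols, collapse = ", ")))
  }
  sub <- data[, c(response, factors, coords)]
  if (anyNA(sub)) {
    bad <- which(rowSums(is.na(sub)) > 0)
    lab <- if (id %in% names(data)) data[[id]][bad] else bad
    abort(sprintf(
      "Missing covariate cells for community(ies): %s.",
      paste(utils::head(lab, 5), collapse = ", ")
    ))
  }
  n <- nrow(data)
  p <- length(factors)
  if (n < p + 5) {
    abort(sprintf("Need at least p + 5 = %d communities, got %d.", p + 5, n))
  }
  structure(
    list(
      y = data[[response]],
      X = data[, factors],
      coords = as.matrix(data[, coords]),
      ids = if (id %in% names(data)) data[[id]] else seq_len(n),
      factors = factors,
      response = response,
      season = season
    ),
    class = "model_frame"
  )
}

#' @export
print.model_frame <- function(x, ...) {
  cat(sprintf(
    "<model_frame> %d communities x %d factors (%s)\n",
    length(x$y), length(x$factors),
    if (is.na(x$season)) "unlabeled" else x$season
  ))
  invisible(x)
}

# Subset a model frame by row indices.
frame_subset <- function(frame, idx) {
  structure(
    list(
      y = frame$y[idx], X = frame$X[idx, , drop = FALSE],
      coords = frame$coords[idx, , drop = FALSE], ids = frame$ids[idx],
      factors = frame$factors, response = frame$response,
      season = frame$season
    ),
    class = "model_frame"
  )
}

#' Modelling frames from a synthetic city
#'
#' Builds a [model_frame()] for one season (covariates and latent
#' emotion of that season) or for the pooled annual scenario
#' (season-averaged covariates and latent emotion). The response is the
#' city's latent negative emotion — the noisy ground-truth signal —
#' unless an indicator table from the post/KDE pathway is supplied via
#' `indicator`.
#'
#' @param city A [generate_city()] result.
#' @param scenario `"annual"` or a season id.
#' @param indicator Optional tibble from [community_emotion_index()]
#'   (matched on `community_id`); its `index` column then becomes the
#'   response.
#' @return A [model_frame()].
#' @export
city_model_frame <- function(city, scenario = "annual", indicator = NULL) {
  stopifnot(inherits(city, "synthetic_city"))
  if (!scenario %in% c("annual", SEASONS)) {
    abort("`scenario` must be 'annual' or a season id.")
  }
  cov <- city$covariates
  lat <- city$latent
  if (scenario == "annual") {
    cov <- cov |>
      group_by(.data$community_id) |>
      summarise(across(dplyr::all_of(FACTOR_NAMES), mean), .groups = "drop")
    lat <- lat |>
      group_by(.data$community_id) |>
      summarise(latent = mean(.data$latent), .groups = "drop")
  } else {
    cov <- cov[cov$season == scenario, ]
    lat <- lat[lat$season == scenario, ]
  }
  d <- cov |>
    left_join(lat, by = "community_id") |>
    left_join(
      city$communities[, c("id", "x", "y")],
      by = c(community_id = "id")
    )
  response <- "latent"
  if (!is.null(indicator)) {
    d <- left_join(d, indicator[, c("community_id", "index")], by = "community_id")
    if (anyNA(d$index)) abort("Indicator table does not cover all communities.")
    response <- "index"
  }
  model_frame(d, response = response, season = scenario)
}
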