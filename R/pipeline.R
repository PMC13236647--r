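# Config-driven orchestration of the full study design: data (synthetic
# or files), seasonal emotion indicators, spatial autocorrelation, model
# comparison, and interpretation outputs, with a machine-readable run
# manifest.

# Schema: every known key with its default. `NULL` defaults mean
# "computed later"; required keys are listed separately.
config_schema <- function() {
  list(
    mode = NULL, # required: "synthetic" or "files"
    out_dir = NULL, # required
    seed = 1,
    seasons = SEASONS,
    city = list(
      n_communities = 300, extent = c(30000, 30000), n_regions = 2,
      n_clusters = 8, cluster_sd = 2500, post_rate = 50, noise_sd = 0.08,
      year = 2022
    ),
    kde = list(bandwidth = 1000, cell_size = 250, kernel = "quartic"),
    weights = list(k = 8, n_perm = 999, alpha = 0.05),
    model = list(
      bandwidth = NULL, kernel = "bisquare", num_trees = 500,
      min_node_size = 3, evaluation_mode = "spatial_cv", folds = 5,
      min_local = 30
    ),
    explain = list(
      n_samples = 64, max_obs = 60, max_background = 15, pdp_grid = 15,
      pdp_factors = c("ndvi", "access_green"),
      effect_factors = c("ndvi", "access_green"),
      dominant_n_samples = 32, dominant_max_obs = 6,
      dominant_max_background = 12
    ),
    files = list(posts = NULL, communities = NULL, covariates = NULL)
  )
}

required_keys <- c("mode", "out_dir")

#' Validate and resolve a pipeline configuration
#'
#' Checks a raw configuration (a named list, or a YAML file path)
#' against the published schema: unknown keys are rejected with a
#' closest-match suggestion, required keys must be present, and every
#' omitted option is filled with its documented default so the resolved
#' configuration is self-describing. All violations are reported
#' together, not just the first.
#'
#' @param raw Named list or path to a YAML file.
#' @return A resolved `run_config` list.
#' @export
validate_config <- function(raw) {
  if (is.character(raw) && length(raw) == 1) raw <- yaml::read_yaml(raw)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) abort("Configuration must be a named list or YAML file.")
  schema <- config_schema()
  errors <- character(0)
  suggest <- function(key, known) {
    hit <- agrep(key, known, max.distance = 0.25, value = TRUE)
    if (length(hit) > 0) sprintf(" (did you mean '%s'?)", hit[1]) else ""
  }
  for (key in names(raw)) {
    if (!key %in% names(schema)) {
      errors <- c(errors, sprintf(
        "unknown key '%s'%s", key, suggest(key, names(schema))
      ))
    }
  }
  for (key in required_keys) {
    if (is.null(raw[[key]])) {
      errors <- c(errors, sprintf("required key '%s' is missing", key))
    }
  }
  resolved <- schema
  for (key in intersect(names(raw), names(schema))) {
    if (is.list(schema[[key]]) && !is.null(names(schema[[key]]))) {
      sub <- raw[[key]]
      if (!is.list(sub)) {
        errors <- c(errors, sprintf("'%s' must be a list of options", key))
        next
      }
      for (sk in names(sub)) {
        if (!sk %in% names(schema[[key]])) {
          errors <- c(errors, sprintf(
            "unknown key '%s.%s'%s", key, sk, suggest(sk, names(schema[[key]]))
          ))
        } else {
          resolved[[key]][[sk]] <- sub[[sk]]
        }
      }
    } else {
      resolved[[key]] <- raw[[key]]
    }
  }
  if (!is.null(resolved$mode) && !resolved$mode %in% c("synthetic", "files")) {
    errors <- c(errors, "'mode' must be 'synthetic' or 'files'")
  }
  if (!is.null(resolved$seasons)) {
    bad <- setdiff(resolved$seasons, SEASONS)
    if (length(bad) > 0) {
      errors <- c(errors, sprintf("unknown season(s): %s", paste(bad, collapse = ", ")))
    }
  }
  if (identical(resolved$mode, "files")) {
    for (f in c("posts", "communities", "covariates")) {
      if (is.null(resolved$files[[f]])) {
        errors <- c(errors, sprintf("files mode requires 'files.%s'", f))
      }
    }
  }
  if (length(errors) > 0) {
    abort(c("Invalid configuration:", setNames(errors, rep("x", length(errors)))))
  }
  structure(resolved, class = "run_config")
}

write_table <- function(x, dir, name, files) {
  path <- file.path(dir, name)
  readr::write_csv(x, path)
  c(files, path)
}

#' Run the full analysis pipeline
#'
#' Executes the study design end to end: (1) obtain data — generate a
#' synthetic city or read post/community/covariate files; (2) build the
#' seasonal and annual population-standardized negative-emotion
#' indicators via KDE; (3) quantify spatial clustering of the annual
#' indicator (global Moran's I and LISA); (4) fit and compare RF, GWR
#' and GWRF across the seasonal and annual scenarios; (5) interpret —
#' global Shapley importance per scenario, seasonal partial-dependence
#' curves, per-community dominant factors and signed local effect
#' surfaces from the annual GWRF. All outputs are flat files under
#' `out_dir`; a manifest (JSON) records the resolved configuration,
#' derived stage seeds, output checksums and stage timings. Identical
#' configurations and master seeds yield identical tabular outputs.
#'
#' @param config A raw configuration list/YAML path (validated first) or
#'   a resolved `run_config`.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- validate_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  master <- config$seed
  files <- character(0)
  timings <- list()
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      abort(sprintf("Stage '%s' failed: %s", name, conditionMessage(e)))
    })
    timings[[name]] <<- round(as.numeric(Sys.time() - t0, units = "secs"), 3)
    message(sprintf("[greenmood] stage '%s' done (%.1fs)", name, timings[[name]]))
    res
  }

  # ---- stage: data -------------------------------------------------
  dat <- stage("data", {
    if (config$mode == "synthetic") {
      cc <- config$city
      city <- generate_city(city_config(
        n_communities = cc$n_communities, extent = cc$extent,
        n_regions = cc$n_regions, n_clusters = cc$n_clusters,
        cluster_sd = cc$cluster_sd, post_rate = cc$post_rate,
        noise_sd = cc$noise_sd, year = cc$year,
        seed = derive_seed(master, "city")
      ))
      posts <- bind_rows(lapply(config$seasons, function(s) {
        generate_posts(city, s, seed = derive_seed(master, paste0("posts_", s)))
      }))
      communities <- city$communities[, c("id", "x", "y", "population")]
      covariates <- city$covariates
      list(city = city, posts = posts, communities = communities,
           covariates = covariates)
    } else {
      posts <- readr::read_csv(config$files$posts, show_col_types = FALSE)
      communities <- readr::read_csv(config$files$communities, show_col_types = FALSE)
      covariates <- readr::read_csv(config$files$covariates, show_col_types = FALSE)
      list(city = NULL, posts = posts, communities = communities,
           covariates = covariates)
    }
  })

  # ---- stage: indicators -------------------------------------------
  ext <- if (config$mode == "synthetic") {
    config$city$extent
  } else {
    c(max(dat$communities$x) * 1.05, max(dat$communities$y) * 1.05)
  }
  g <- grid_spec(ext, config$kde$cell_size)
  indicators <- stage("indicators", {
    per_season <- lapply(config$seasons, function(s) {
      ev <- negative_events(dat$posts, s)
      if (nrow(ev) == 0) {
        abort(sprintf("No negative posts in season '%s'.", s))
      }
      surf <- kde_surface(ev, g, config$kde$bandwidth, config$kde$kernel)
      community_emotion_index(surf, dat$communities, season = s)
    })
    names(per_season) <- config$seasons
    all_neg <- dat$posts[dat$posts$sentiment == "negative", c("x", "y")]
    surf_all <- kde_surface(all_neg, g, config$kde$bandwidth, config$kde$kernel)
    annual <- community_emotion_index(surf_all, dat$communities, season = "annual")
    c(per_season, list(annual = annual))
  })
  files <- write_table(bind_rows(indicators), config$out_dir, "indicators.csv", files)

  # ---- stage: autocorrelation --------------------------------------
  autoc <- stage("autocorrelation", {
    coords <- dat$communities[, c("x", "y")]
    W <- build_weights(coords, "knn", k = config$weights$k)
    idx <- indicators$annual$index
    gm <- global_morans_i(idx, W, n_perm = config$weights$n_perm,
      seed = derive_seed(master, "moran"))
    ls <- local_morans_i(idx, W, alpha = config$weights$alpha,
      n_perm = config$weights$n_perm, seed = derive_seed(master, "lisa"))
    list(global = gm, lisa = ls)
  })
  files <- write_table(glance(autoc$global), config$out_dir, "moran.csv", files)
  lisa_tab <- bind_cols(
    tibble(community_id = dat$communities$id), as_tibble(autoc$lisa)[, -1]
  )
  files <- write_table(lisa_tab, config$out_dir, "lisa.csv", files)
  if (config$mode == "synthetic") {
    gj <- file.path(config$out_dir, "communities_lisa.geojson")
    write_communities_geojson(dat$city, gj, properties = lisa_tab)
    files <- c(files, gj)
  }

  # ---- stage: modelling frames -------------------------------------
  scenarios <- c(config$seasons, "annual")
  frames <- stage("frames", {
    out <- lapply(scenarios, function(sc) {
      cov <- dat$covariates
      if (sc == "annual") {
        cov <- cov |>
          group_by(.data$community_id) |>
          summarise(across(dplyr::all_of(FACTOR_NAMES), mean), .groups = "drop")
      } else {
        cov <- cov[cov$season == sc, setdiff(names(cov), "season")]
      }
      d <- indicators[[sc]] |>
        select("community_id", "index") |>
        left_join(cov, by = "community_id") |>
        left_join(
          dat$communities |> select(community_id = "id", "x", "y"),
          by = "community_id"
        )
      model_frame(d, response = "index", season = sc)
    })
    names(out) <- scenarios
    out
  })

  # ---- stage: model comparison -------------------------------------
  comparison <- stage("models", {
    compare_models(
      frames,
      bandwidth = config$model$bandwidth, kernel = config$model$kernel,
      num_trees = config$model$num_trees,
      min_node_size = config$model$min_node_size,
      evaluation_mode = config$model$evaluation_mode,
      folds = config$model$folds, min_local = config$model$min_local,
      seed = derive_seed(master, "compare")
    )
  })
  files <- write_table(comparison, config$out_dir, "model_comparison.csv", files)

  # ---- stage: explanation ------------------------------------------
  expl <- stage("explain", {
    ex <- config$explain
    importance <- bind_rows(lapply(scenarios, function(sc) {
      fr <- frames[[sc]]
      rf <- fit_global_rf(fr, num_trees = config$model$num_trees,
        min_node_size = config$model$min_node_size,
        seed = derive_seed(master, paste0("rf_", sc)))
      n_fr <- nrow(fr$X)
      obs <- if (n_fr > ex$max_obs) {
        with_seed(derive_seed(master, paste0("shapobs_", sc)),
          sort(sample.int(n_fr, ex$max_obs)))
      } else {
        seq_len(n_fr)
      }
      att <- shapley_attribution(
        function(X) predict(rf, X), fr$X[obs, , drop = FALSE],
        background = fr$X,
        n_samples = ex$n_samples, max_background = ex$max_background,
        seed = derive_seed(master, paste0("shap_", sc))
      )
      mutate(global_importance(att), scenario = sc, .before = 1)
    }))
    pdp <- bind_rows(lapply(config$seasons, function(sc) {
      fr <- frames[[sc]]
      rf <- fit_global_rf(fr, num_trees = config$model$num_trees,
        min_node_size = config$model$min_node_size,
        seed = derive_seed(master, paste0("rf_", sc)))
      bind_rows(lapply(ex$pdp_factors, function(f) {
        mutate(
          partial_dependence(function(X) predict(rf, X), fr$X, f,
            grid_size = ex$pdp_grid),
          season = sc, .before = 1
        )
      }))
    }))
    n_annual <- length(frames$annual$y)
    gwrf <- fit_gwrf(
      frames$annual,
      bandwidth = min(n_annual,
        config$model$bandwidth %||% max(config$model$min_local, round(n_annual / 5))),
      kernel = config$model$kernel, num_trees = config$model$num_trees,
      min_node_size = config$model$min_node_size,
      min_local = min(config$model$min_local, n_annual),
      seed = derive_seed(master, "gwrf_annual")
    )
    dom <- local_dominant_factors(
      gwrf, n_samples = ex$dominant_n_samples, max_obs = ex$dominant_max_obs,
      max_background = ex$dominant_max_background,
      seed = derive_seed(master, "dominant")
    )
    effects <- bind_rows(lapply(ex$effect_factors, function(f) {
      mutate(local_effect_surface(gwrf, f), factor = f, .before = 1)
    }))
    list(importance = importance, pdp = pdp, dominant = dom, effects = effects)
  })
  files <- write_table(expl$importance, config$out_dir, "importance.csv", files)
  files <- write_table(expl$pdp, config$out_dir, "pdp.csv", files)
  files <- write_table(expl$dominant$communities, config$out_dir,
    "dominant_factors.csv", files)
  files <- write_table(expl$dominant$shares, config$out_dir,
    "dominant_shares.csv", files)
  files <- write_table(expl$effects, config$out_dir, "local_effects.csv", files)
  if (config$mode == "synthetic") {
    gj <- file.path(config$out_dir, "dominant_factors.geojson")
    write_communities_geojson(dat$city, gj, properties = expl$dominant$communities)
    files <- c(files, gj)
  }

  # ---- manifest ----------------------------------------------------
  cfg_path <- file.path(config$out_dir, "resolved_config.yaml")
  yaml::write_yaml(unclass(config), cfg_path)
  manifest <- list(
    package_version = as.character(utils::packageVersion("greenmood")),
    config_hash = unname(tools::md5sum(cfg_path)),
    master_seed = master,
    outputs = lapply(sort(files), function(f) {
      list(file = basename(f), md5 = unname(tools::md5sum(f)))
    }),
    timings = timings
  )
  jsonlite::write_json(
    manifest, file.path(config$out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  invisible(manifest)
}
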