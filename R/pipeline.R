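#' Default run configuration
#'
#' All tunable parameters of the pipeline in one nested list: every stage
#' consumes its parameters from this object only. Round-trips losslessly
#' through JSON or YAML.
#'
#' @param seed Master seed for the run.
#' @return Nested list of class `run_config`.
#' @export
default_config <- function(seed = 1L) {
  structure(list(
    seed = as.integer(seed),
    temporal_enabled = TRUE,
    schedule = list(
      subjects = 5, baseline_collections = 4, interval_min = 15,
      phase_durations = list(I = 75, II = 60, III = 120, IV = 60)
    ),
    simulate = list(
      n_features = 10529, archetype_fraction = 0.7, noise_cv = 0.2,
      tic_spread = 0.15, drift_amplitude = 0.1, subject_cv = 0.2,
      missing_rate = 0.02
    ),
    preprocess = list(intensity_threshold = 500, loess_span = 0.75, pool = TRUE),
    fcm = list(
      c = 16, m = 1.5, c_grid = c(8, 12, 16, 20), m_grid = c(1.25, 1.5, 2),
      select = FALSE, tol = 1e-6, max_iter = 200, n_init = 10
    ),
    labeling = list(threshold = 0.5, dominant_k = 4, dominant_override = NULL),
    spatial = list(
      enabled = FALSE, width = 40, height = 40, n_peaks = 285,
      tolerance = 0.180, min_freq = 0.0384, k = 3, fc_threshold = 1,
      n_up = 21, n_down = 29, effect_log2fc = 2, noise_cv = 0.02
    ),
    enrich = list(alpha = 0.01)
  ), class = c("run_config", "list"))
}

#' Read / write a run configuration
#'
#' @param config A `run_config`.
#' @param path JSON (`.json`) or YAML (`.yml`/`.yaml`) file path.
#' @return `path` invisibly / the restored `run_config`.
#' @export
write_config <- function(config, path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("The yaml package is required for YAML configs.")
    }
    yaml::write_yaml(unclass(config), path)
  } else {
    jsonlite::write_json(unclass(config), path,
      auto_unbox = TRUE, pretty = TRUE, digits = NA, null = "null"
    )
  }
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort("The yaml package is required for YAML configs.")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  cfg$fcm$c_grid <- as.numeric(cfg$fcm$c_grid)
  cfg$fcm$m_grid <- as.numeric(cfg$fcm$m_grid)
  structure(cfg, class = c("run_config", "list"))
}

#' Run the end-to-end pipeline
#'
#' Executes simulate -> preprocess -> cluster -> label -> statistics (and
#' optionally the spatial branch) under one configuration, writing every
#' intermediate as CSV plus a provenance manifest with content hashes.
#' Deterministic under a fixed config.
#'
#' @param config A `run_config` (see [default_config()]).
#' @param out_dir Output directory (created if needed); `NULL` keeps results
#'   in memory only.
#' @param table An existing `feature_table` to analyse instead of simulating
#'   one.
#' @param pathways Optional pathway map (named list or two-column data
#'   frame) switching on the enrichment stage.
#' @param quiet Suppress stage progress messages.
#' @return List of class `pipeline_result` with the artifacts of every
#'   executed stage.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL,
                         table = NULL, pathways = NULL, quiet = TRUE) {
  stage <- function(name) if (!quiet) message("[strokemap] stage: ", name)
  res <- list(config = config)

  run_stage <- function(name, expr) {
    stage(name)
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  sc <- config$schedule
  schedule <- run_stage("schedule", build_schedule(
    subjects = sc$subjects, baseline_collections = sc$baseline_collections,
    interval_min = sc$interval_min,
    phase_durations = unlist(sc$phase_durations)
  ))
  res$schedule <- schedule

  temporal <- !isFALSE(config$temporal_enabled)
  if (temporal && is.null(table)) {
    sim <- config$simulate
    table <- run_stage("simulate", simulate_feature_table(
      schedule,
      n_features = sim$n_features,
      archetype_fraction = sim$archetype_fraction,
      noise_cv = sim$noise_cv, tic_spread = sim$tic_spread,
      drift_amplitude = sim$drift_amplitude, subject_cv = sim$subject_cv,
      missing_rate = sim$missing_rate, seed = config$seed
    ))
  }
  res$table <- table

  if (temporal) {
  pp <- config$preprocess
  processed <- run_stage("preprocess", preprocess_pipeline(
    table,
    intensity_threshold = pp$intensity_threshold,
    span = pp$loess_span, pool = pp$pool
  ))
  res$processed <- processed

  fc <- config$fcm
  x <- processed$values
  if (isTRUE(fc$select)) {
    sel <- run_stage("select_parameters", select_parameters(
      x,
      c_grid = fc$c_grid, m_grid = fc$m_grid, seed = config$seed,
      tol = fc$tol, max_iter = fc$max_iter, n_init = fc$n_init
    ))
    res$selection <- sel
    fc$c <- sel$c_opt
    fc$m <- sel$m_opt
  }
  fit <- run_stage("cluster", fit_fcm(
    x,
    c = fc$c, m = fc$m, seed = config$seed,
    tol = fc$tol, max_iter = fc$max_iter, n_init = fc$n_init
  ))
  codes <- assign_cluster_codes(fit$centroids, schedule)
  colnames(fit$memberships) <- codes
  rownames(fit$centroids) <- codes
  ord <- order(codes)
  fit$memberships <- fit$memberships[, ord, drop = FALSE]
  fit$centroids <- fit$centroids[ord, , drop = FALSE]
  res$fit <- fit

  lb <- config$labeling
  annotations <- run_stage("annotate", annotate_clusters(fit$centroids, schedule))
  dominant <- lb$dominant_override %||%
    identify_dominant(fit$memberships, k = lb$dominant_k)
  labels <- run_stage("label", assign_labels(
    fit$memberships, annotations, dominant, threshold = lb$threshold
  ))
  res$annotations <- annotations
  res$dominant <- dominant
  res$labels <- labels

  stats <- run_stage("stats", trajectory_stats(table, schedule))
  res$stats <- stats

  if (!is.null(pathways)) {
    selected <- labels$feature_id[labels$selected]
    res$enrichment <- run_stage("enrich", fisher_ora(
      selected = intersect(selected, all_pathway_features(pathways)),
      background = intersect(labels$feature_id, all_pathway_features(pathways)),
      pathways = pathways, alpha = config$enrich$alpha
    ))
  }
  } # end temporal branch

  if (isTRUE(config$spatial$enabled)) {
    sp <- config$spatial
    grid <- run_stage("spatial_simulate", simulate_pixel_grid(
      width = sp$width, height = sp$height, n_peaks = sp$n_peaks,
      n_up = sp$n_up, n_down = sp$n_down,
      effect_log2fc = sp$effect_log2fc, noise_cv = sp$noise_cv,
      seed = config$seed
    ))
    bins <- run_stage("spatial_bin", bin_peaks(
      grid,
      tolerance = sp$tolerance, min_freq = sp$min_freq
    ))
    res$grid <- grid
    res$bins <- bins
    res$segmentation <- run_stage(
      "spatial_cluster",
      cluster_pixels(rms_normalize(bins), k = sp$k)
    )
    res$differential <- run_stage("spatial_differential", roi_differential(
      bins, bins$pixels$lesion, bins$pixels$contra,
      fc_threshold = sp$fc_threshold
    ))
  }

  class(res) <- "pipeline_result"
  if (!is.null(out_dir)) write_pipeline_result(res, out_dir)
  res
}

all_pathway_features <- function(pathways) {
  if (is.data.frame(pathways)) unique(pathways[[1]]) else unique(unlist(pathways))
}

#' Write pipeline artifacts with a provenance manifest
#'
#' @param res A `pipeline_result`.
#' @param out_dir Output directory.
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_result <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  if (!is.null(res$table)) write_feature_table(res$table, p("table"))
  if (!is.null(res$processed)) {
    readr::write_csv(
      tibble::as_tibble(res$processed$values, rownames = "feature_id"),
      p("processed.csv")
    )
  }
  if (!is.null(res$fit)) {
    write_fcm_model(res$fit, p("fcm_model.json"))
    readr::write_csv(
      tibble::as_tibble(res$fit$memberships, rownames = "feature_id"),
      p("memberships.csv")
    )
  }
  if (!is.null(res$labels)) {
    readr::write_csv(
      dplyr::select(res$labels, -"above_threshold"),
      p("labels.csv")
    )
  }
  if (!is.null(res$stats)) readr::write_csv(res$stats, p("trajectory_stats.csv"))
  if (!is.null(res$enrichment)) readr::write_csv(res$enrichment, p("enrichment.csv"))
  if (!is.null(res$bins)) {
    readr::write_csv(res$bins$bins, p("spatial_bins.csv"))
    readr::write_csv(res$segmentation$labels, p("spatial_labels.csv"))
    readr::write_csv(res$differential, p("spatial_differential.csv"))
  }
  write_config(res$config, p("config.json"))
  files <- setdiff(list.files(out_dir, full.names = TRUE), p("provenance.json"))
  manifest <- list(
    config_hash = unname(tools::md5sum(p("config.json"))),
    seed = res$config$seed,
    r_version = as.character(getRversion()),
    files = purrr::map(
      setNames(files, basename(files)),
      ~ list(md5 = unname(tools::md5sum(.x)), bytes = file.size(.x))
    )
  )
  jsonlite::write_json(manifest, p("provenance.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat("  stages:", paste(setdiff(names(x), "config"), collapse = ", "), "\n")
  if (!is.null(x$fit)) {
    cat(sprintf(
      "  clustering: c=%d, m=%.3g, XB=%.4g; dominant set {%s}\n",
      x$fit$c, x$fit$m, x$fit$xb, paste(x$dominant, collapse = ", ")
    ))
  }
  invisible(x)
}
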