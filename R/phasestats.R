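#' Per-phase means of a trajectory
#'
#' Arithmetic mean of a trajectory's values within each phase block of the
#' schedule. Every collection contributes to exactly one phase.
#'
#' @param traj Numeric vector over the schedule's collections (one value per
#'   collection; pool across subjects first with [pool_subjects()] for
#'   multi-subject tables).
#' @param schedule A `phase_schedule`.
#' @return Tibble with `phase` and `mean`.
#' @export
phase_means <- function(traj, schedule = build_schedule()) {
  if (length(traj) != n_collections(schedule)) {
    abort(sprintf(
      "Trajectory length (%d) does not match the schedule's %d collections.",
      length(traj), n_collections(schedule)
    ))
  }
  tibble::tibble(value = traj, phase = schedule$phase) |>
    dplyr::group_by(.data$phase) |>
    dplyr::summarise(mean = mean(.data$value), .groups = "drop")
}

#' Key-time fold change of a trajectory
#'
#' Ratio of the trajectory's mean over its key (signature) phase to its mean
#' over the baseline phase. When `key_phase` is omitted, the phase containing
#' the trajectory's maximum is used. Several phases may be given jointly
#' (e.g. `c("IIIA", "IIIB")` for a plateau spanning the ischemia block).
#'
#' @param traj Numeric vector over the schedule's collections.
#' @param schedule A `phase_schedule`.
#' @param key_phase Phase name(s) defining the signature window, or `NULL`.
#' @param baseline_phase Baseline phase (default `"I"`, the pre-occlusion
#'   collections).
#' @return Positive scalar fold change.
#' @export
key_time_fold_change <- function(traj, schedule = build_schedule(),
                                 key_phase = NULL, baseline_phase = "I") {
  if (length(traj) != n_collections(schedule)) {
    abort("Trajectory length does not match the schedule.")
  }
  ph <- as.character(schedule$phase)
  stopifnot(baseline_phase %in% ph)
  base <- mean(traj[ph == baseline_phase])
  if (!is.finite(base) || base <= 0) {
    abort("Baseline phase mean is not positive; gap-fill or offset the trajectory first.")
  }
  if (is.null(key_phase)) {
    key_phase <- ph[which.max(traj)]
  }
  if (!all(key_phase %in% ph)) {
    abort(sprintf("Unknown key phase %s.", paste(setdiff(key_phase, ph), collapse = ", ")))
  }
  mean(traj[ph %in% key_phase]) / base
}

#' Global temporal fluctuation (SD energy) of a trajectory
#'
#' The standard deviation of the trajectory across all collections — the
#' magnitude of its global temporal fluctuation. Zero iff the trajectory is
#' constant.
#'
#' @param traj Non-empty numeric vector.
#' @return Non-negative scalar.
#' @export
sd_energy <- function(traj) {
  stopifnot(length(traj) >= 1)
  if (length(traj) == 1) return(0)
  sd(traj)
}

#' Trajectory statistics for every feature of a table
#'
#' Pools each feature across subjects to its per-timepoint mean trajectory,
#' then computes phase means, SD energy, the key phase (phase of the
#' trajectory maximum) and the key-time fold change versus baseline.
#'
#' @param table A `feature_table` (or a features x collections matrix).
#' @param schedule A `phase_schedule` (taken from the table if omitted).
#' @param baseline_phase Baseline phase for the fold change.
#' @return Tibble with one row per feature: `feature_id`, `mean_I` ...
#'   `mean_IV`, `sd_energy`, `key_phase`, `key_time_fc`.
#' @export
trajectory_stats <- function(table, schedule = NULL, baseline_phase = "I") {
  if (inherits(table, "feature_table")) {
    schedule <- schedule %||% table$schedule
    pooled <- pool_subjects(table)
  } else {
    stopifnot(is.matrix(table))
    schedule <- schedule %||% build_schedule()
    pooled <- table
  }
  ph <- as.character(schedule$phase)
  phase_mean_mat <- vapply(PHASE_LEVELS[PHASE_LEVELS %in% ph], function(p) {
    rowMeans(pooled[, ph == p, drop = FALSE])
  }, numeric(nrow(pooled)))
  base <- phase_mean_mat[, baseline_phase]
  if (any(base <= 0)) {
    abort("Some features have non-positive baseline means; gap-fill first.")
  }
  key_idx <- apply(pooled, 1, which.max)
  key_phase <- ph[key_idx]
  key_fc <- phase_mean_mat[cbind(seq_len(nrow(pooled)), match(key_phase, colnames(phase_mean_mat)))] / base
  out <- tibble::tibble(
    feature_id = rownames(pooled) %||% sprintf("F%05d", seq_len(nrow(pooled)))
  )
  for (p in colnames(phase_mean_mat)) out[[paste0("mean_", p)]] <- unname(phase_mean_mat[, p])
  out$sd_energy <- unname(apply(pooled, 1, sd))
  out$key_phase <- key_phase
  out$key_time_fc <- unname(key_fc)
  out
}

#' Join trajectory statistics with kinetic labels
#'
#' One row per feature combining the masked primary kinetic label with SD
#' energy and key-time fold change — the per-pathway reporting table.
#'
#' @param stats A [trajectory_stats()] tibble.
#' @param labels An [assign_labels()] tibble.
#' @param features Optional character vector restricting the report to a
#'   feature subset (e.g. one pathway's members).
#' @return Tibble sorted by descending key-time fold change.
#' @export
pathway_trajectory_table <- function(stats, labels, features = NULL) {
  if (!is.null(features)) {
    orphans <- setdiff(features, stats$feature_id)
    if (length(orphans) > 0) {
      abort(sprintf(
        "Features absent from the statistics table: %s",
        paste(head(orphans, 5), collapse = ", ")
      ))
    }
    stats <- dplyr::filter(stats, .data$feature_id %in% features)
  }
  orphans <- setdiff(stats$feature_id, labels$feature_id)
  if (length(orphans) > 0) {
    abort(sprintf(
      "Features without labels: %s",
      paste(head(orphans, 5), collapse = ", ")
    ))
  }
  stats |>
    dplyr::left_join(
      dplyr::select(
        labels, "feature_id", "masked_primary", "selected",
        dplyr::any_of("annotation")
      ),
      by = "feature_id"
    ) |>
    dplyr::arrange(dplyr::desc(.data$key_time_fc))
}
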