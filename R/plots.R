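#' Plot cluster centroid trajectories
#'
#' One panel per cluster showing the centroid trajectory over the
#' collections, with phase blocks shaded.
#'
#' @param object An `fcm_fit`.
#' @param schedule A `phase_schedule` matching the centroid length.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fcm_fit
#' @export
autoplot.fcm_fit <- function(object, schedule = build_schedule(), ...) {
  cl <- cluster_ids(object)
  df <- tibble::as_tibble(object$centroids, .name_repair = ~ sprintf("C%02d", seq_along(.x))) |>
    dplyr::mutate(cluster = cl) |>
    tidyr::pivot_longer(-"cluster", names_to = "col", values_to = "value") |>
    dplyr::mutate(collection_index = as.integer(sub("^C", "", .data$col)) - 1L) |>
    dplyr::left_join(
      tibble::as_tibble(schedule)[, c("collection_index", "phase")],
      by = "collection_index"
    )
  ggplot2::ggplot(df, ggplot2::aes(.data$collection_index, .data$value)) +
    ggplot2::geom_line(ggplot2::aes(colour = .data$phase, group = 1)) +
    ggplot2::facet_wrap(~cluster) +
    ggplot2::labs(
      x = "collection index", y = "standardized intensity",
      colour = "phase"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a pixel segmentation as a label map
#'
#' @param object A `segmentation_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot segmentation_result
#' @export
autoplot.segmentation_result <- function(object, ...) {
  ggplot2::ggplot(
    object$labels,
    ggplot2::aes(.data$x, .data$y, fill = factor(.data$cluster))
  ) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = "cluster") +
    ggplot2::theme_minimal()
}

#' Plot pooled feature trajectories by phase
#'
#' @param table A `feature_table`.
#' @param features Character vector of feature ids to draw.
#' @return A ggplot object.
#' @export
plot_trajectories <- function(table, features) {
  stopifnot(inherits(table, "feature_table"))
  pooled <- pool_subjects(table)
  missing <- setdiff(features, rownames(pooled))
  if (length(missing) > 0) {
    abort(sprintf("Unknown features: %s", paste(head(missing, 5), collapse = ", ")))
  }
  sched <- tibble::as_tibble(table$schedule)
  df <- tibble::as_tibble(pooled[features, , drop = FALSE], rownames = "feature_id") |>
    tidyr::pivot_longer(-"feature_id", names_to = "col", values_to = "intensity") |>
    dplyr::mutate(collection_index = as.integer(sub("^C", "", .data$col))) |>
    dplyr::left_join(sched[, c("collection_index", "time_min", "phase")],
      by = "collection_index"
    )
  ggplot2::ggplot(df, ggplot2::aes(.data$time_min, .data$intensity,
    colour = .data$feature_id
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$phase)) +
    ggplot2::labs(x = "time (min)", y = "pooled intensity") +
    ggplot2::theme_minimal()
}

#' Bar plot of pathway enrichment results
#'
#' @param enrichment A [fisher_ora()] tibble.
#' @param max_pathways Number of top pathways to show.
#' @return A ggplot object.
#' @export
plot_enrichment <- function(enrichment, max_pathways = 20) {
  df <- head(dplyr::arrange(enrichment, .data$p_value), max_pathways)
  ggplot2::ggplot(df, ggplot2::aes(
    -log10(.data$p_value),
    stats::reorder(.data$pathway_id, -.data$p_value),
    fill = .data$pass
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(x = expression(-log[10] ~ p), y = NULL, fill = "p < alpha") +
    ggplot2::theme_minimal()
}
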