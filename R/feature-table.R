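#' Construct a feature table
#'
#' The central exchange object of the temporal pipeline: a features x samples
#' intensity matrix together with per-sample and per-feature metadata and a
#' log of the preprocessing steps applied so far.
#'
#' @param intensities Numeric matrix, features in rows (rownames = feature
#'   ids), samples in columns (colnames = sample ids). `NA` marks missing
#'   values; present values must be non-negative.
#' @param samples Tibble with one row per column of `intensities`; must
#'   contain `sample_id`, `subject`, `collection_index`, `injection_order`,
#'   `phase`.
#' @param features Tibble with one row per row of `intensities`; must contain
#'   a unique `feature_id` and may carry `mz`, pathway ids and generator
#'   ground-truth columns.
#' @param schedule The `phase_schedule` the samples follow.
#' @param transform_log Character vector of applied processing steps.
#'
#' @return Object of class `feature_table`.
#' @export
feature_table <- function(intensities, samples, features, schedule,
                          transform_log = character()) {
  stopifnot(is.matrix(intensities))
  if (is.null(rownames(intensities))) rownames(intensities) <- features$feature_id
  if (is.null(colnames(intensities))) colnames(intensities) <- samples$sample_id
  if (nrow(samples) != ncol(intensities)) {
    abort("sample metadata must cover every column of the intensity matrix.")
  }
  if (nrow(features) != nrow(intensities)) {
    abort("feature metadata must cover every row of the intensity matrix.")
  }
  if (anyDuplicated(features$feature_id)) abort("feature ids must be unique.")
  if (any(intensities < 0, na.rm = TRUE)) {
    abort("intensities must be non-negative where present.")
  }
  structure(
    list(
      intensities = intensities,
      samples = tibble::as_tibble(samples),
      features = tibble::as_tibble(features),
      schedule = schedule,
      transform_log = transform_log
    ),
    class = "feature_table"
  )
}

log_step <- function(table, step) {
  table$transform_log <- c(table$transform_log, step)
  table
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf(
    "<feature_table> %d features x %d samples (%d subjects)\n",
    nrow(x$intensities), ncol(x$intensities),
    dplyr::n_distinct(x$samples$subject)
  ))
  n_na <- sum(is.na(x$intensities))
  if (n_na > 0) cat(sprintf("  missing cells: %d\n", n_na))
  if (length(x$transform_log)) {
    cat("  transform log:", paste(x$transform_log, collapse = " -> "), "\n")
  }
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$intensities)

#' Long-format view of a feature table
#'
#' @param x A `feature_table`.
#' @param ... Unused.
#' @return Tibble with one row per (feature, sample) cell joined to the
#'   sample metadata.
#' @method as_tibble feature_table
#' @export
as_tibble.feature_table <- function(x, ...) {
  tibble::as_tibble(x$intensities, rownames = "feature_id") |>
    tidyr::pivot_longer(-"feature_id",
      names_to = "sample_id", values_to = "intensity"
    ) |>
    dplyr::left_join(x$samples, by = "sample_id")
}

#' Pool a feature table across subjects
#'
#' Collapses the samples to one mean trajectory per feature: for each
#' collection index, the across-subject mean of the observed intensities.
#'
#' @param table A `feature_table`.
#' @return Numeric matrix, features x collections (columns ordered by
#'   collection index).
#' @export
pool_subjects <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  idx <- sort(unique(table$samples$collection_index))
  pooled <- vapply(idx, function(ci) {
    cols <- table$samples$collection_index == ci
    rowMeans(table$intensities[, cols, drop = FALSE], na.rm = TRUE)
  }, numeric(nrow(table$intensities)))
  colnames(pooled) <- sprintf("C%02d", idx)
  rownames(pooled) <- rownames(table$intensities)
  pooled
}

#' Write / read a feature table as a CSV trio plus provenance JSON
#'
#' The wide intensity matrix, the sample metadata and the feature metadata
#' are written as three CSV files sharing `path` as prefix, and run
#' parameters (if any were attached by the generator) as a JSON sidecar.
#'
#' @param table A `feature_table`.
#' @param path File prefix, e.g. `"out/run1"` writes
#'   `run1_intensities.csv`, `run1_samples.csv`, `run1_features.csv` and
#'   `run1_provenance.json`.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  wide <- tibble::as_tibble(table$intensities, rownames = "feature_id")
  readr::write_csv(wide, paste0(path, "_intensities.csv"))
  readr::write_csv(table$samples, paste0(path, "_samples.csv"))
  readr::write_csv(table$features, paste0(path, "_features.csv"))
  prov <- list(
    transform_log = table$transform_log,
    parameters = attr(table, "parameters"),
    n_features = nrow(table$intensities),
    n_samples = ncol(table$intensities)
  )
  jsonlite::write_json(prov, paste0(path, "_provenance.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_feature_table
#' @param schedule Schedule to attach on read (defaults to reconstructing a
#'   default schedule; supply the original for non-default designs).
#' @export
read_feature_table <- function(path, schedule = build_schedule()) {
  wide <- readr::read_csv(paste0(path, "_intensities.csv"),
    show_col_types = FALSE
  )
  samples <- readr::read_csv(paste0(path, "_samples.csv"),
    show_col_types = FALSE
  ) |>
    dplyr::mutate(phase = factor(.data$phase, levels = PHASE_LEVELS))
  features <- readr::read_csv(paste0(path, "_features.csv"),
    show_col_types = FALSE
  )
  mat <- as.matrix(wide[, -1])
  rownames(mat) <- wide$feature_id
  feature_table(mat, samples, features, schedule)
}
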