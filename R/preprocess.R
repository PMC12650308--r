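#' Filter features by maximum intensity
#'
#' Retains features whose maximum observed intensity strictly exceeds
#' `threshold` counts (the convention for low-signal peak removal).
#'
#' @param table A `feature_table`.
#' @param threshold Intensity threshold in counts.
#' @return Filtered `feature_table`; the numbers retained/dropped are
#'   recorded in the transform log.
#' @export
filter_intensity <- function(table, threshold = 500) {
  stopifnot(inherits(table, "feature_table"), threshold >= 0)
  if (nrow(table$intensities) == 0) abort("Feature table is empty.")
  maxes <- apply(table$intensities, 1, max, na.rm = TRUE)
  keep <- maxes > threshold
  table$intensities <- table$intensities[keep, , drop = FALSE]
  table$features <- table$features[keep, , drop = FALSE]
  log_step(table, sprintf(
    "filter_intensity(threshold=%g, retained=%d, dropped=%d)",
    threshold, sum(keep), sum(!keep)
  ))
}

#' Total-ion-current normalization
#'
#' Scales every sample column so its total intensity equals the
#' across-sample median of the pre-normalization totals. Missing cells are
#' ignored in the totals and stay missing.
#'
#' @param table A `feature_table`.
#' @return Normalized `feature_table`.
#' @export
tic_normalize <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  totals <- colSums(table$intensities, na.rm = TRUE)
  zero <- which(totals <= 0)
  if (length(zero) > 0) {
    abort(sprintf(
      "Sample %s has zero total intensity and cannot be TIC-normalized.",
      colnames(table$intensities)[zero[1]]
    ))
  }
  target <- median(totals)
  table$intensities <- sweep(table$intensities, 2, target / totals, `*`)
  log_step(table, sprintf("tic_normalize(target=%.6g)", target))
}

#' LOESS injection-order drift correction
#'
#' Per feature, fits a locally weighted regression of intensity on injection
#' order over all samples and divides each value by the fitted trend
#' (rescaled to mean 1), removing smooth signal drift while preserving the
#' feature's mean level. Missing cells are excluded from the fit and remain
#' missing; trend values at missing positions are interpolated.
#'
#' @param table A `feature_table`.
#' @param span LOESS span in (0, 1].
#' @return Corrected `feature_table`.
#' @export
loess_batch_correct <- function(table, span = 0.75) {
  stopifnot(inherits(table, "feature_table"))
  if (!(span > 0 && span <= 1)) abort("`span` must be in (0, 1].")
  io <- table$samples$injection_order
  if (length(unique(io)) != length(io) || !setequal(io, seq_along(io))) {
    abort("injection_order must be a permutation of the sample indices.")
  }
  n <- length(io)
  if (n * span < 4) {
    abort("Too few samples for the local fit; use a larger span.")
  }
  ord <- order(io)
  x <- table$intensities
  for (i in seq_len(nrow(x))) {
    y <- x[i, ord]
    obs <- which(!is.na(y))
    if (length(obs) < 4) next
    fit <- lowess(obs, y[obs], f = span)
    trend <- approx(fit$x, fit$y, xout = seq_len(n), rule = 2)$y
    trend <- pmax(trend, 1e-8 * mean(y[obs]))
    x[i, ord] <- y / (trend / mean(trend))
  }
  table$intensities <- x
  log_step(table, sprintf("loess_batch_correct(span=%g)", span))
}

#' Gap filling of missing intensities
#'
#' Replaces each feature's missing cells with half its minimum observed
#' value, the conservative limit-of-detection convention. Features with no
#' observed value at all are dropped with a warning.
#'
#' @param table A `feature_table`.
#' @return Gap-filled `feature_table` with no missing entries.
#' @export
gap_fill <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  x <- table$intensities
  all_na <- rowSums(!is.na(x)) == 0
  if (any(all_na)) {
    warn(sprintf(
      "Dropping %d feature(s) with no observed values: %s",
      sum(all_na),
      paste(head(rownames(x)[all_na], 5), collapse = ", ")
    ))
    x <- x[!all_na, , drop = FALSE]
    table$features <- table$features[!all_na, , drop = FALSE]
  }
  n_imputed <- sum(is.na(x))
  if (n_imputed > 0) {
    fill <- apply(x, 1, min, na.rm = TRUE) / 2
    idx <- which(is.na(x), arr.ind = TRUE)
    x[idx] <- fill[idx[, 1]]
  }
  table$intensities <- x
  log_step(table, sprintf(
    "gap_fill(imputed=%d, dropped_features=%d)", n_imputed, sum(all_na)
  ))
}

#' Per-feature standardization for shape-based clustering
#'
#' Z-scores every feature row (mean 0, unit standard deviation) so that
#' Euclidean distances between features compare trajectory shapes rather
#' than abundances. Constant features cannot be standardized; they are
#' excluded and listed.
#'
#' @param x A gap-filled `feature_table`, or a bare numeric matrix
#'   (features x samples or features x pooled collections).
#' @return Object of class `processed_matrix`: list with `values` (the
#'   standardized matrix), `excluded` (ids of constant features) and
#'   `transform_log`.
#' @export
standardize <- function(x) {
  if (inherits(x, "feature_table")) {
    if (anyNA(x$intensities)) {
      abort("standardize() requires a gap-filled table with no missing values.")
    }
    mat <- x$intensities
    tl <- x$transform_log
  } else {
    stopifnot(is.matrix(x))
    if (anyNA(x)) abort("standardize() requires a matrix with no missing values.")
    mat <- x
    tl <- character()
  }
  mu <- rowMeans(mat)
  sdv <- apply(mat, 1, sd)
  constant <- sdv < 1e-12
  out <- (mat[!constant, , drop = FALSE] - mu[!constant]) / sdv[!constant]
  structure(
    list(
      values = out,
      excluded = rownames(mat)[constant] %||% which(constant),
      transform_log = c(tl, sprintf(
        "standardize(excluded_constant=%d)", sum(constant)
      ))
    ),
    class = "processed_matrix"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.processed_matrix <- function(x, ...) {
  cat(sprintf(
    "<processed_matrix> %d features x %d columns (z-scored; %d constant excluded)\n",
    nrow(x$values), ncol(x$values), length(x$excluded)
  ))
  invisible(x)
}

#' Run the full temporal preprocessing chain
#'
#' Convenience wrapper applying, in order: intensity filtering, TIC
#' normalization, LOESS injection-order correction, gap filling, subject
#' pooling (optional) and standardization.
#'
#' @param table A `feature_table`.
#' @param intensity_threshold Counts threshold for [filter_intensity()].
#' @param span LOESS span.
#' @param pool Pool per-timepoint means across subjects before
#'   standardization (recommended for trajectory clustering).
#' @return A `processed_matrix`.
#' @export
preprocess_pipeline <- function(table, intensity_threshold = 500,
                                span = 0.75, pool = TRUE) {
  out <- table |>
    filter_intensity(intensity_threshold) |>
    tic_normalize() |>
    loess_batch_correct(span = span) |>
    gap_fill()
  if (pool) {
    pm <- standardize(pool_subjects(out))
    pm$transform_log <- c(
      out$transform_log, "pool_subjects()",
      pm$transform_log[length(pm$transform_log)]
    )
    pm
  } else {
    standardize(out)
  }
}
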