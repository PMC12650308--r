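#' Build a phase-aligned microdialysis collection schedule
#'
#' Lays out the serial dialysate collections of an occlusion/reperfusion
#' experiment on a common time axis and assigns each collection to one of the
#' five experimental phases: I (probe implantation / baseline), II (filament
#' insertion surgery), IIIA (early ischemia), IIIB (late ischemia) and IV
#' (reperfusion). The ischemia block is split evenly into IIIA and IIIB.
#'
#' The default configuration reproduces the canonical 5-subject design: a
#' 75-min phase I (whose last four collections are the pre-occlusion baseline
#' samples), 60 min of surgery, 120 min of ischemia and 60 min of
#' reperfusion, sampled every 15 min, i.e. 21 collections per subject and 105
#' samples in total.
#'
#' @param subjects Number of subjects (animals).
#' @param baseline_collections Number of pre-occlusion baseline collections;
#'   must fit inside phase I.
#' @param interval_min Collection interval in minutes.
#' @param phase_durations Named numeric vector of phase durations in minutes
#'   with names `I`, `II`, `III`, `IV`. Each must be a positive multiple of
#'   `interval_min`; the `III` block must split into two equal
#'   interval-aligned halves.
#'
#' @return A tibble of class `phase_schedule` with one row per collection:
#'   `collection_index` (0-based), `time_min`, `phase` (factor with levels
#'   I, II, IIIA, IIIB, IV). Attributes: `subject_count`, `interval_min`,
#'   `baseline_collections`.
#' @examples
#' sched <- build_schedule()
#' table(sched$phase)
#' @export
build_schedule <- function(subjects = 5,
                           baseline_collections = 4,
                           interval_min = 15,
                           phase_durations = c(I = 75, II = 60, III = 120, IV = 60)) {
  stopifnot(subjects >= 1, interval_min > 0, baseline_collections >= 1)
  required <- c("I", "II", "III", "IV")
  if (!all(required %in% names(phase_durations))) {
    abort("`phase_durations` must be named with phases I, II, III and IV.")
  }
  phase_durations <- phase_durations[required]
  for (p in required) {
    d <- phase_durations[[p]]
    if (d <= 0 || d %% interval_min != 0) {
      abort(sprintf(
        "Duration of phase %s (%g min) is not a positive multiple of the %g-min interval.",
        p, d, interval_min
      ))
    }
  }
  if ((phase_durations[["III"]] / 2) %% interval_min != 0) {
    abort(sprintf(
      "Duration of phase III (%g min) cannot be split into two equal interval-aligned halves.",
      phase_durations[["III"]]
    ))
  }

  durations <- c(
    I    = phase_durations[["I"]],
    II   = phase_durations[["II"]],
    IIIA = phase_durations[["III"]] / 2,
    IIIB = phase_durations[["III"]] / 2,
    IV   = phase_durations[["IV"]]
  )
  counts <- durations / interval_min
  n <- sum(counts)
  if (baseline_collections > counts[["I"]]) {
    abort(sprintf(
      "baseline_collections (%d) exceeds the %d collections available in phase I.",
      baseline_collections, counts[["I"]]
    ))
  }

  out <- tibble::tibble(
    collection_index = seq_len(n) - 1L,
    time_min = (seq_len(n) - 1L) * interval_min,
    phase = factor(rep(PHASE_LEVELS, times = counts), levels = PHASE_LEVELS)
  )
  structure(
    out,
    subject_count = as.integer(subjects),
    interval_min = interval_min,
    baseline_collections = as.integer(baseline_collections),
    class = c("phase_schedule", class(out))
  )
}

#' Number of collections per subject in a schedule
#' @param schedule A `phase_schedule`.
#' @return Integer count.
#' @export
n_collections <- function(schedule) nrow(schedule)

#' Expand a schedule into a per-sample metadata sheet
#'
#' Crosses the per-subject schedule with the subject roster. Injection order
#' defaults to acquisition subject-by-subject in collection order.
#'
#' @param schedule A `phase_schedule`.
#' @return Tibble with `sample_id`, `subject`, `collection_index`,
#'   `injection_order`, `time_min`, `phase`.
#' @export
sample_sheet <- function(schedule) {
  stopifnot(inherits(schedule, "phase_schedule"))
  subjects <- attr(schedule, "subject_count")
  out <- tidyr::expand_grid(
    subject = seq_len(subjects),
    collection_index = schedule$collection_index
  ) |>
    dplyr::left_join(
      tibble::as_tibble(schedule)[, c("collection_index", "time_min", "phase")],
      by = "collection_index"
    ) |>
    dplyr::mutate(
      sample_id = sprintf("S%d_C%02d", .data$subject, .data$collection_index),
      injection_order = dplyr::row_number()
    ) |>
    dplyr::select(
      "sample_id", "subject", "collection_index",
      "injection_order", "time_min", "phase"
    )
  out
}

## collection indices bracketing each phase transition, e.g. the last
## phase-II and first phase-IIIA collection for the "II/III" boundary
phase_boundaries <- function(schedule) {
  ph <- as.character(schedule$phase)
  idx <- schedule$collection_index
  cuts <- which(ph[-1] != ph[-length(ph)])
  purrr::map(cuts, function(i) {
    list(
      before = ph[i], after = ph[i + 1],
      indices = c(idx[i], idx[i + 1]),
      token = boundary_token(ph[i], ph[i + 1])
    )
  })
}

boundary_token <- function(before, after) {
  ## II -> IIIA is spoken of as the "II/III" boundary; likewise IIIB -> IV
  b <- sub("^III[AB]$", "III", c(before, after))
  if (b[1] == b[2]) paste0(before, "/", after) else paste0(b[1], "/", b[2])
}

#' @export
print.phase_schedule <- function(x, ...) {
  cat(sprintf(
    "<phase_schedule> %d subjects x %d collections (every %g min)\n",
    attr(x, "subject_count"), nrow(x), attr(x, "interval_min")
  ))
  tab <- table(x$phase)
  cat("  collections per phase:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  invisible(x)
}
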