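#' Simulate a temporal microdialysis feature table
#'
#' Generates a features x samples intensity table with the statistical
#' structure the temporal pipeline assumes: a configurable fraction of
#' features following the sixteen kinetic archetypes (assigned round-robin so
#' archetypes are balanced), the remainder flat null features; per-subject
#' log-normal scale heterogeneity; multiplicative log-normal measurement
#' noise; a per-sample total-ion-current factor; a smooth per-feature-weighted
#' injection-order drift; and limit-of-detection-style missingness injected
#' among each feature's low-intensity cells. Planted fold-change events
#' override a feature's shape so that its key-phase/baseline mean ratio
#' equals the requested fold change exactly before noise.
#'
#' @param schedule A [build_schedule()] result.
#' @param n_features Number of features (default mirrors the 10,529 retained
#'   annotated features of the reference design).
#' @param archetype_fraction Fraction of features assigned an archetype.
#' @param noise_cv Coefficient of variation of the multiplicative log-normal
#'   measurement noise.
#' @param tic_spread CV of the per-sample total-ion-current factor.
#' @param drift_amplitude Relative amplitude of the linear injection-order
#'   drift; each feature responds with its own weight in `[0.5, 1]` times
#'   this amplitude.
#' @param subject_cv CV of the per-subject log-normal scale factor.
#' @param missing_rate Expected fraction of cells set missing per feature;
#'   missing cells are drawn from the cells below the feature's median
#'   noise-free intensity (dropout mimics limit-of-detection censoring).
#' @param planted_events Optional tibble with columns `feature` (feature id),
#'   `phase` (a phase name, or several separated by `"+"`, e.g.
#'   `"IIIA+IIIB"`), `fold_change` (> 0).
#' @param seed Integer seed; identical seeds give bit-identical tables.
#'
#' @return A `feature_table` whose `features` tibble carries ground-truth
#'   columns `archetype`, `base_abundance`, `drift_weight`, `planted_phase`,
#'   `planted_fc`.
#' @examples
#' sched <- build_schedule(subjects = 2)
#' ft <- simulate_feature_table(sched, n_features = 40, seed = 1)
#' ft
#' @export
simulate_feature_table <- function(schedule = build_schedule(),
                                   n_features = 10529,
                                   archetype_fraction = 0.7,
                                   noise_cv = 0.2,
                                   tic_spread = 0.15,
                                   drift_amplitude = 0.1,
                                   subject_cv = 0.2,
                                   missing_rate = 0.02,
                                   planted_events = NULL,
                                   seed = 1L) {
  stopifnot(
    n_features >= 1,
    archetype_fraction >= 0, archetype_fraction <= 1,
    noise_cv >= 0, tic_spread >= 0, drift_amplitude >= 0,
    subject_cv >= 0, missing_rate >= 0, missing_rate <= 1
  )
  set.seed(seed)
  samples <- sample_sheet(schedule)
  n_samp <- nrow(samples)
  n_coll <- n_collections(schedule)
  codes <- archetype_specs()$code

  n_arch <- round(n_features * archetype_fraction)
  archetype <- c(
    rep(codes, length.out = n_arch),
    rep(NA_character_, n_features - n_arch)
  )
  feature_id <- sprintf("F%05d", seq_len(n_features))

  templates <- vapply(codes, archetype_template,
    numeric(n_coll),
    schedule = schedule
  )
  shapes <- matrix(1, n_features, n_coll)
  has_arch <- !is.na(archetype)
  shapes[has_arch, ] <- t(templates[, archetype[has_arch], drop = FALSE])

  planted_phase <- rep(NA_character_, n_features)
  planted_fc <- rep(NA_real_, n_features)
  if (!is.null(planted_events)) {
    planted_events <- tibble::as_tibble(planted_events)
    ph <- as.character(schedule$phase)
    for (i in seq_len(nrow(planted_events))) {
      f <- planted_events$feature[i]
      row <- match(f, feature_id)
      if (is.na(row)) abort(sprintf("Planted event references unknown feature %s.", f))
      phases <- strsplit(planted_events$phase[i], "+", fixed = TRUE)[[1]]
      if (!all(phases %in% PHASE_LEVELS)) {
        abort(sprintf(
          "Planted event for %s references unknown phase %s.",
          f, planted_events$phase[i]
        ))
      }
      fc <- planted_events$fold_change[i]
      stopifnot(fc > 0)
      ## rectangular event: baseline 1 everywhere, fc on the key collections,
      ## so mean(key)/mean(phase I) = fc exactly before noise
      shapes[row, ] <- ifelse(ph %in% phases, fc, 1)
      planted_phase[row] <- planted_events$phase[i]
      planted_fc[row] <- fc
      archetype[row] <- NA_character_
    }
  }

  base_abundance <- rlnorm(n_features, meanlog = log(5000), sdlog = 1)
  drift_weight <- runif(n_features, 0.5, 1)
  subj_scale <- lognormal_cv(dplyr::n_distinct(samples$subject), subject_cv)
  tic_factor <- lognormal_cv(n_samp, tic_spread)
  io <- samples$injection_order
  drift_shape <- 2 * (io - 1) / (n_samp - 1) - 1 # linear -1..1, smooth in order

  coll_col <- match(samples$collection_index, schedule$collection_index)
  x <- shapes[, coll_col, drop = FALSE] * base_abundance
  x <- sweep(x, 2, subj_scale[samples$subject], `*`)
  x <- sweep(x, 2, tic_factor, `*`)
  x <- x * (1 + drift_amplitude * outer(drift_weight, drift_shape))
  if (noise_cv > 0) {
    sdl <- sqrt(log(1 + noise_cv^2))
    x <- x * matrix(rlnorm(length(x), -sdl^2 / 2, sdl), nrow(x))
  }

  n_missing_planted <- 0L
  if (missing_rate > 0) {
    for (i in seq_len(n_features)) {
      k <- stats::rbinom(1, n_samp, missing_rate)
      k <- min(k, n_samp - 1L) # keep at least one observed value
      if (k == 0) next
      low <- which(x[i, ] <= quantile(x[i, ], 0.5))
      miss <- sample(low, min(k, length(low)))
      x[i, miss] <- NA_real_
      n_missing_planted <- n_missing_planted + length(miss)
    }
  }

  rownames(x) <- feature_id
  colnames(x) <- samples$sample_id
  features <- tibble::tibble(
    feature_id = feature_id,
    mz = round(runif(n_features, 70, 1300), 4),
    archetype = archetype,
    base_abundance = base_abundance,
    drift_weight = drift_weight,
    planted_phase = planted_phase,
    planted_fc = planted_fc
  )
  out <- feature_table(x, samples, features, schedule)
  attr(out, "parameters") <- list(
    n_features = n_features, archetype_fraction = archetype_fraction,
    noise_cv = noise_cv, tic_spread = tic_spread,
    drift_amplitude = drift_amplitude, subject_cv = subject_cv,
    missing_rate = missing_rate, seed = seed,
    n_missing_planted = n_missing_planted
  )
  out
}

## log-normal draws with unit mean and the requested coefficient of variation
lognormal_cv <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdl <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdl^2 / 2, sdlog = sdl)
}
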