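# Shared fixtures, all built in code at test time.

default_sched <- build_schedule()

# tiny single-subject table with known values: 3 features x 21 collections
tiny_table <- function(values = NULL, subjects = 1) {
  sched <- build_schedule(subjects = subjects)
  samples <- sample_sheet(sched)
  n <- nrow(samples)
  if (is.null(values)) {
    values <- rbind(
      seq_len(n) * 10,
      rep(100, n),
      1000 + 5 * sin(seq_len(n))
    )
  }
  ids <- sprintf("F%05d", seq_len(nrow(values)))
  dimnames(values) <- list(ids, samples$sample_id)
  feature_table(values, samples, tibble::tibble(feature_id = ids), sched)
}

# zero-noise archetype table: `copies` features per archetype
archetype_table <- function(copies = 5, noise_cv = 0, seed = 42, ...) {
  simulate_feature_table(
    default_sched,
    n_features = 16 * copies, archetype_fraction = 1,
    noise_cv = noise_cv, tic_spread = 0, drift_amplitude = 0,
    subject_cv = 0, missing_rate = 0, seed = seed, ...
  )
}

# membership matrix with known structure: block-diagonal-ish soft labels
toy_memberships <- function(n_per = 10, c = 4, sharpness = 0.8, seed = 1) {
  set.seed(seed)
  u <- matrix(runif(n_per * c * c, 0, 1 - sharpness), n_per * c, c)
  for (k in seq_len(c)) u[(k - 1) * n_per + seq_len(n_per), k] <- sharpness
  u <- u / rowSums(u)
  colnames(u) <- LETTERS[seq_len(c)]
  rownames(u) <- sprintf("F%05d", seq_len(nrow(u)))
  u
}
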