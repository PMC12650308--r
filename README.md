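# strokemap

Spatiotemporal metabolic trajectory mapping for cerebral
ischemia–reperfusion studies.

## What it is for

Transient middle-cerebral-artery occlusion/reperfusion (MCAO/R) experiments
monitor the brain interstitial metabolome through microdialysis: serial
dialysate collections every 15 minutes across five experimental phases —
probe implantation (I), occlusion surgery (II), early/late ischemia
(IIIA/IIIB), reperfusion (IV) — profiled by LC-MS into intensities over
~10,000 metabolic features. `strokemap` is for researchers analysing such
time-resolved metabolomics (and the companion MALDI-imaging sections): it
assigns every feature a kinetic label from a 16-trajectory taxonomy,
quantifies phase-aligned fold changes, segments imaging pixels into tissue
classes, and tests pathway over-representation — all driven from tibbles and
reproducible under a single seed.

At the core is fuzzy c-means clustering of standardized trajectories
$x_i$ with fuzzifier $m > 1$:

$$u_{ik} = \Big[\sum_{j=1}^{c}\big(\lVert x_i - v_k\rVert/\lVert x_i - v_j\rVert\big)^{2/(m-1)}\Big]^{-1},\qquad v_k = \frac{\sum_i u_{ik}^m x_i}{\sum_i u_{ik}^m},$$

with the cluster count $c$ and $m$ chosen jointly by minimizing the
Xie–Beni validity index

$$XB = \frac{\sum_i\sum_k u_{ik}^m\,\lVert x_i - v_k\rVert^2}{n\cdot\min_{k\neq l}\lVert v_k - v_l\rVert^2}.$$

Soft memberships are then turned into interpretable labels with a
*drowning-effect* correction: the clusters absorbing the most membership
mass (whole-run drifts and fluctuating backgrounds) are set aside, and each
feature's primary characteristic is its argmax membership over the
remaining clusters, with features selected for presentation when a
non-dominant membership strictly exceeds 0.5.

A bundled synthetic-data generator emulates the 5-subject × 21-collection
design — 16 planted kinetic archetypes, log-normal noise, total-ion-current
variation, injection-order drift, limit-of-detection dropout, planted
fold-change events — so the whole pipeline is testable without any data
download. Everything the generator plants, the pipeline must recover; that
contract is what the test suite asserts.

## Worked example

```r
library(strokemap)

sched <- build_schedule()
sched
#> <phase_schedule> 5 subjects x 21 collections (every 15 min)
#>   collections per phase: I=5 II=4 IIIA=4 IIIB=4 IV=4

# 50 copies of each of the 16 kinetic archetypes, mild measurement noise
ft <- simulate_feature_table(sched, n_features = 800, archetype_fraction = 1,
                             noise_cv = 0.05, tic_spread = 0,
                             drift_amplitude = 0, subject_cv = 0,
                             missing_rate = 0, seed = 11)
ft
#> <feature_table> 800 features x 105 samples (5 subjects)

# pool across subjects, standardize, and pick (c, m) by Xie-Beni
pm  <- standardize(pool_subjects(ft))
sel <- select_parameters(pm$values, c_grid = c(8, 12, 16, 20),
                         m_grid = c(1.25, 1.5, 2), seed = 11, n_init = 5)
fit <- fit_fcm(pm$values, c = sel$c_opt, m = sel$m_opt, seed = 11, n_init = 5)
glance(fit)
#> # A tibble: 1 × 7
#>       c     m     n objective     xb n_iter converged
#>   <int> <dbl> <int>     <dbl>  <dbl>  <int> <lgl>
#> 1    16     2   800      82.9 0.0456      7 TRUE
```

The grid search recovers the 16 planted archetypes ($c^\* = 16$) and the
fit converges with a Xie–Beni score of 0.046 — tight clusters, well
separated. Labelling and a planted reperfusion surge:

```r
colnames(fit$memberships) <- assign_cluster_codes(fit$centroids, sched)
identify_dominant(fit$memberships, 4)   # clusters absorbing the most mass
#> [1] "N" "I" "M" "F"

# a urea-like surge: planted 10-fold rise in reperfusion vs baseline
ev  <- tibble::tibble(feature = "F00001", phase = "IV", fold_change = 10)
ft2 <- simulate_feature_table(sched, n_features = 50, archetype_fraction = 0.5,
                              noise_cv = 0.1, planted_events = ev, seed = 1)
key_time_fold_change(pool_subjects(ft2)["F00001", ], sched, key_phase = "IV")
#> [1] 10.44889
```

The pooled key-time fold change (phase-IV mean over phase-I baseline mean)
recovers the planted 10-fold surge to within 5% at 10% measurement noise.
The spatial branch works the same way: `simulate_pixel_grid()` →
`bin_peaks()` (±0.180 Da, ≥3.84% detection) → `rms_normalize()` →
`cluster_pixels()` (cosine/Ward) → `roi_differential()` (|log2FC| > 1
between the lesion and its contralateral mirror). `run_pipeline()` chains
everything under one config with a hashed provenance manifest, and
`autoplot()` methods draw centroid trajectories and segmentation maps.

See the methods vignette (`vignettes/trajectory-mapping.Rmd`) for the
models, parameter meanings and design choices.

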