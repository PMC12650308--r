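---
title: "Spatiotemporal metabolic trajectory mapping: models and methods"
author: "strokemap authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatiotemporal metabolic trajectory mapping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strokemap)
```

# The problem

Transient middle-cerebral-artery occlusion with reperfusion (MCAO/R) in the
rodent is the standard model of ischemic stroke. Its metabolic consequences
unfold on a minute-to-hour scale across five experimental phases: probe
implantation (I), filament-insertion surgery (II), early and late ischemia
(IIIA, IIIB), and reperfusion (IV). Microdialysis probes sample the brain
interstitial fluid serially — here every 15 minutes, 21 collections per
subject, five subjects, 105 dialysate samples — and LC-MS metabolomics turns
each collection into an intensity over ~10,000 metabolic features. The
analytical task is to assign each feature a *kinetic label*: which of a
small taxonomy of temporal trajectories (declines during implantation, peaks
at phase boundaries, reperfusion surges, whole-run drifts, ...) it follows,
and with what confidence. A companion spatial task segments MALDI-imaging
pixel spectra of brain sections into tissue classes and contrasts the
metabolically abnormal region against its contralateral mirror.

`strokemap` implements this pipeline end to end on tabular data, with a
synthetic-data generator that reproduces the study geometry so that every
stage can be exercised and validated without any external download.

# Study schedule

`build_schedule()` lays the collections on the phase axis. The canonical
timing is 1 h of surgery, 2 h of ischemia and 1 h of reperfusion at 15-min
collections. A 21-collection day at that interval spans 315 min, so phase I
is given 75 min (5 collections); its last four collections are the
pre-occlusion baseline samples. The ischemia block is split evenly into
IIIA and IIIB at its midpoint, since "early" and "late" ischemia carry no
published boundary time. All of this is configurable; the constraints
(durations are positive multiples of the interval, the ischemia block splits
evenly, the baseline fits inside phase I) are validated with informative
errors.

```{r}
sched <- build_schedule()
sched
```

# The synthetic-data generator

The generator defines the study conditions under which the pipeline is
tested. `simulate_feature_table()` builds a features × samples table as

$$x_{ij} = b_i \, s_i(t_j) \, a_{\mathrm{subj}(j)} \, g_j \,
  \big(1 + A w_i \delta_j\big) \, \varepsilon_{ij},$$

where $b_i$ is a log-normal base abundance (median 5000 counts, geometric SD
$e$), $s_i(t)$ the feature's kinetic shape, $a$ a per-subject log-normal
scale (CV 0.2 by default — the five animals are biological replicates
without a published variance model), $g_j$ a per-sample total-ion-current
factor (CV 0.15), $\delta_j$ a linear injection-order drift of relative
amplitude $A$ (default 0.1) with a per-feature sensitivity weight
$w_i \sim U(0.5, 1)$, and $\varepsilon$ multiplicative log-normal
measurement noise (CV 0.2 by default). Missing values are injected at a
configurable rate among each feature's low-intensity cells, mimicking
limit-of-detection dropout. Defaults for the noise knobs are fixed once at
values typical for LC-MS microdialysis data; the feature count defaults to
10,529, the number of annotated features retained in the reference design
(one published summary rounds this to 10,429; the per-method figure is
used).

Two design choices deserve a note:

* **Per-feature drift weights.** A drift factor applied uniformly to a whole
  sample is indistinguishable from a TIC fluctuation and is removed exactly
  by TIC normalization. Real injection-order drift is feature-dependent
  (ionization and stability differ per analyte), so each feature responds to
  the common drift curve with its own weight; this leaves the LOESS stage
  real work to do.
* **Rectangular planted events.** A planted fold-change event (e.g. a
  reperfusion urea surge of FC 10, or an ischemic citrulline-like plateau of
  FC 6 spanning the full 2-h ischemia block) replaces the shape by a step
  function equal to the fold change on the key phase. Mean(key)/mean(baseline)
  then equals the requested fold change *exactly* before noise, which gives
  downstream statistics a sharp ground truth.

## The sixteen kinetic archetypes

Sixteen trajectory archetypes A–P span the taxonomy of kinetic signatures:
ramps and spikes during implantation, single and twin peaks inside phases,
boundary peaks at II/III and III/IV, a reperfusion ramp and decline,
fluctuating and whole-run monotone backgrounds. Templates are the simplest
shapes realizing each verbal description — piecewise-linear ramps and
Gaussian bumps anchored to the phase blocks, on a positive baseline of 1 —
so they adapt to any schedule. `archetype_specs()` lists each code with the
annotation its template must receive; `check_template()` verifies the
qualitative dynamics declaratively, and the test suite asserts all sixteen,
plus their mutual separation after standardization.

```{r, fig.width=7, fig.height=4}
plot(archetype_template("E", sched), type = "b",
     xlab = "collection", ylab = "relative intensity",
     main = "Archetype E: peak at the II/III boundary")
```

# Temporal preprocessing

The chain is `filter_intensity()` (drop features whose maximum never
strictly exceeds 500 counts), `tic_normalize()`, `loess_batch_correct()`,
`gap_fill()`, `standardize()`; `preprocess_pipeline()` runs it in order and
each step appends itself to the table's transform log. Choices made where
the convention is not fully pinned down:

* TIC normalization scales every sample to the **median** of the raw totals
  — a scale-stable target that leaves data on the original intensity scale.
* The LOESS correction regresses each feature on injection order over **all
  samples pooled** (no dedicated QC-injection scheme is assumed; if your
  design has QC injections, correct on those upstream). The fit uses a span
  of 0.75 and the correction is divisive — intensities are multiplicative —
  with the trend rescaled to mean 1 so the feature's average level is
  preserved. Trends are clamped away from zero to keep the division safe.
* Gap filling imputes **half the feature's minimum observed value**, the
  conservative limit-of-detection convention. Features with no observed
  values are dropped with a warning.
* Standardization z-scores each feature so that Euclidean distances compare
  trajectory *shapes*, not abundances — without it, clustering on raw
  intensities would group features by magnitude and contradict a shape-based
  taxonomy. Constant features cannot be z-scored and are excluded and
  listed.

For trajectory clustering the pipeline pools samples to per-timepoint means
across subjects (21-point trajectories) before standardizing. Pooling
averages out subject-level scale heterogeneity and reduces the clustering
dimension; the clustering functions are dimension-agnostic, so the
unpooled 105-sample vectors can be clustered instead by passing
`pool = FALSE`.

# Fuzzy c-means with Xie–Beni model selection

Soft clustering is the methodological core. With standardized trajectories
$x_i$, centroids $v_k$, and fuzzifier $m > 1$:

$$u_{ik} = \Big[\sum_{j=1}^{c}
  \big(\lVert x_i - v_k\rVert / \lVert x_i - v_j\rVert\big)^{2/(m-1)}\Big]^{-1},
\qquad
v_k = \frac{\sum_i u_{ik}^m x_i}{\sum_i u_{ik}^m},$$

alternated until the largest membership change falls below $10^{-6}$ (cap
200 iterations). The objective $J_m = \sum_{i,k} u_{ik}^m \lVert x_i -
v_k\rVert^2$ is non-increasing across iterations and is asserted so in the
tests. Numerical corner cases: distances are normalized by the row minimum
before the $-1/(m-1)$ power, so fuzzifiers near 1 (exponents near $-100$) do
not overflow; a point coinciding with one or more centroids splits its
membership equally among them (the singular case of the formula, resolved by
symmetry); a cluster losing all weight is re-seeded from the farthest point.

Each fit takes the best of `n_init` restarts by final $J_m$. The first
restart uses deterministic farthest-point (maximin) seeding — on
well-separated data it covers every group essentially surely — and the
remainder use k-means++-style distance-weighted draws. All randomness flows
from one seed, so fits are bit-reproducible.

Cluster count $c$ and fuzzifier $m$ are chosen jointly by minimizing the
Xie–Beni index

$$XB = \frac{\sum_i \sum_k u_{ik}^m \lVert x_i - v_k \rVert^2}
           {n \cdot \min_{k \neq l} \lVert v_k - v_l \rVert^2},$$

the ratio of fuzzy compactness to worst-case centroid separation (lower is
better). `select_parameters()` scans a grid, reports the full table for
inspection, and breaks ties toward smaller $c$, then smaller $m$. A
degenerate fit with coincident centroids (typical when $c$ overshoots the
true structure) has zero separation; `xie_beni()` raises on it, and the fit
records $XB = \infty$ so the grid search simply never selects it. The
package default grid is $c \in \{8, 12, 16, 20\}$ and
$m \in \{1.25, 1.5, 2\}$ — a desk-scale grid that brackets both the published
cluster count (16) and the soft/hard assignment regimes; on planted
16-archetype data the search selects $c = 16$ across seeds.

# Kinetic labelling and the drowning-effect correction

`annotate_clusters()` turns each centroid into a (peak location, trend)
annotation via a fixed decision ladder, with margins in standardized units:

1. constant profiles → *fluctuating / none*;
2. whole-run monotone: Spearman $|\rho| \ge 0.8$ **and** at least a quarter
   of the variation in each half of the run (rank correlation alone is
   fooled by a one-phase ramp with a long shallow tail) → *increase* /
   *decrease throughout*;
3. first/final-phase ramps: monotone within the phase
   ($|\rho| \ge 0.9$, range ≥ 1 z) and flat elsewhere (range ≤ 0.5 z);
4. a census of comparable local maxima (within 1 z of the global maximum,
   after 3-point smoothing): three or more → *fluctuating*; two →
   *biphasic*; one → *peak*, located on the boundary token when the argmax
   falls on either collection flanking a phase transition, otherwise on its
   phase.

Letter codes are assigned by `assign_cluster_codes()`: clusters are ordered
by the time of their dominant feature (argmax for peaks, phase midpoint for
phase-restricted ramps; biphasic before single peaks at ties), with
fluctuating profiles next and whole-run trends last (decrease before
increase), and lettered A, B, C, ... in that order. This is a reproducible,
purely algorithmic lettering in the narrative style of kinetic-signature
taxonomies; it approximates but does not promise any particular manual
lettering (boundary peaks and in-phase peaks interleave differently in
published narratives than under a strict timeline sort).

Soft clustering on this kind of data shows a *drowning effect*: a few
clusters (typically the whole-run monotone and fluctuating backgrounds)
absorb large membership mass and mask features' distinctive dynamics.
`identify_dominant()` makes the dominant set algorithmic — the $k = 4$
clusters with the largest total membership $\sum_i u_{ik}$, with an explicit
override for a manually chosen set — and `assign_labels()` computes each
feature's *masked primary*: the argmax of its membership row over the
non-dominant clusters, alongside the unmasked argmax. A feature is selected
for presentation iff some non-dominant membership strictly exceeds 0.5. Raw
(not mask-renormalized) memberships are compared against the threshold; the
renormalized alternative would select more features and can be obtained by
rescaling the rows first. `hca_on_memberships()` clusters features in
membership space (Ward on Euclidean distances) and serializes the dendrogram
to Newick.

# Trajectory statistics

For the pooled trajectory of each feature, `trajectory_stats()` reports
per-phase means, the **key-time fold change** — mean over the signature
phase (by default the phase containing the maximum; any phase set can be
given, e.g. `c("IIIA", "IIIB")` for a plateau) divided by the phase-I
baseline mean — and the **SD energy**, defined here as the standard
deviation of the trajectory across all collections. "SD energy" is used in
the field as a label for global temporal fluctuation without a printed
formula; the standard deviation is the simplest statistic with the right
invariances (zero iff constant, mirror-symmetric, scale-equivariant), and it
is reported *alongside* the fold change, never as a ratio of the two.
Fold changes pool across subjects by per-timepoint means; per-subject values
can be computed by subsetting the table. At the default noise level
(CV 0.1) the pooled fold change of a planted FC-10 event stays within ±20%
of truth in well over 95% of seeded replicates (asserted over 200 replicates
in the tests).

# Spatial segmentation and ROI differential analysis

`bin_peaks()` reduces per-pixel peak lists to a pixels × bins matrix:
consensus centres are found by greedy intensity-ordered grouping (the
strongest unclaimed peak founds a bin and claims everything within ±0.180
Da), each pixel contributes the maximum-intensity peak inside the interval,
and bins detected in fewer than 3.84% of pixels are dropped — the
detection-frequency reading of the vendor's "lower-bound 3.84" retention
rule. Optional 3-point moving-average smoothing runs along the m/z axis per
spectrum before binning (spectral, not spatial, denoising).
`rms_normalize()` scales each pixel to unit root-mean-square intensity.

`cluster_pixels()` segments pixels by agglomerative clustering under cosine
dissimilarity with Ward's linkage — the Lance–Williams Ward update applied
directly to the cosine dissimilarities, replicating the behavior of the
imaging software this reproduces. Ward's method formally presumes Euclidean
geometry; using it on cosine dissimilarities is a faithful-reproduction
choice, not a geometric endorsement. `roi_differential()` compares mean bin
intensities between two disjoint pixel masks as
$\log_2\!\big((\bar{x}_A + \epsilon)/(\bar{x}_B + \epsilon)\big)$ with a
pseudocount $\epsilon$ defaulting to 1% of the global median positive
intensity (zero-intensity contralateral pixels would otherwise produce
infinities), flagging bins whose absolute log2 fold change strictly
exceeds 1.

# Pathway over-representation

`fisher_ora()` tests each user-supplied pathway for enrichment in a selected
feature set with the one-sided Fisher's exact test — computed as the
hypergeometric upper tail — against the annotated background (all features
carrying a pathway annotation, the usual convention). The pass flag uses the
raw $p < 0.01$ rule; a Benjamini–Hochberg column is emitted for transparency
but deliberately does not drive the flag. No pathway databases are bundled
or fetched: annotation maps are caller-provided two-column tables.

# One-call pipeline

`run_pipeline()` chains simulate → preprocess → cluster → label → statistics
(plus the spatial branch and enrichment when enabled) under a single
`default_config()` object, writes every intermediate as CSV, and emits a
provenance manifest with an MD5 hash of every output file. Reruns under the
same config are byte-identical. Stage failures abort with the stage name.

```{r, eval = FALSE}
cfg <- default_config(seed = 1)
cfg$simulate$n_features <- 800
res <- run_pipeline(cfg, out_dir = "run1")
autoplot(res$fit, res$schedule)
```

# Problem sizes, what the tests show, and limitations

The test suite and the acceptance script run the pipeline at desk scale:
800 features (50 per archetype) for cluster-count selection, 40×40-pixel
grids with 285 peaks for the spatial branch, 105-sample tables for the
fold-change statistics; the full 10,529-feature table is generated to verify
the study geometry. These sizes were chosen as the smallest at which each
planted structure is unambiguous.

Passing on synthetic data shows that the implementation recovers structure
*it planted itself* under the stated noise model. The generator emulates
multiplicative noise, TIC variation, smooth drift, subject heterogeneity and
LOD dropout; it does not emulate chromatographic artefacts, adducts and
in-source fragments, correlated (pathway-level) noise, heavy-tailed
contamination, or probe-depth drift, so green tests do not certify behavior
under those. Known limitations: the annotation margins (0.5/1.0 z,
$|\rho|$ thresholds) are fixed constants exposed as arguments, calibrated on
the sixteen templates, and may need adjustment for centroids from very noisy
fits; the dominant set defaults to size 4 rather than being inferred; FCM is
plain alternating optimization (no acceleration structures), adequate up to
~10⁴ features × ~10² timepoints but not beyond; and biological
interpretation of the labels is out of scope.
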