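Package: strokemap
Title: Spatiotemporal Metabolic Trajectory Mapping for Cerebral
    Ischemia-Reperfusion Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Analysis toolkit for time-resolved microdialysis metabolomics
    and MALDI mass-spectrometry imaging of middle-cerebral-artery
    occlusion/reperfusion (MCAO/R) experiments. Provides phase-aligned
    study schedules, a synthetic-data generator with planted kinetic
    archetypes, intensity filtering, total-ion-current normalization,
    LOESS injection-order correction and gap filling, fuzzy c-means
    trajectory clustering with Xie-Beni validity-based parameter
    selection, dominant-cluster-corrected kinetic labelling, phase
    fold-change and fluctuation statistics, pixel-level image
    segmentation with region-of-interest differential analysis, and
    Fisher over-representation tests against user-supplied pathway
    annotations.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tools,
    tidyr,
    utils
Suggests:
    e1071,
    mclust,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
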