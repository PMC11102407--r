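Package: shotgunPredict
Title: Predict Shotgun-Comparable Species Abundance Profiles from 16S Amplicon Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Translates species-level 16S rRNA amplicon abundance profiles into
    the species-level profiles that whole-genome shotgun (WGS) sequencing would
    have produced. A linear mixed model with per-species random intercepts,
    fitted by restricted maximum likelihood (REML), corrects platform bias for
    species detected on both platforms (update module) and imputes species seen
    only by WGS from principal-component summaries of the 16S profile
    (imputation module). Includes readers for QIIME2/SILVA- and MetaPhlAn-style
    abundance tables, the normalization chain (relative abundance,
    log10(1e6*x + 1)), fixed-effects and ablation baselines, Pearson/RMSE
    evaluation harnesses, and a paired-cohort simulator for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    lme4,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
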