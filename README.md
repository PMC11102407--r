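# shotgunPredict

Predict species-level whole-genome shotgun (WGS) abundance profiles from 16S
rRNA amplicon data.

## The problem

16S amplicon sequencing is the cheap workhorse of microbiome studies, but it
under-resolves species and misses many taxa that shotgun metagenomics
detects. When the same samples are profiled on both platforms, species fall
into three groups: detected by **both** platforms (with platform-shifted
abundance estimates), by **WGS only**, or by **16S only**. `shotgunPredict`
is for researchers holding 16S tables who want WGS-comparable species-level
profiles: it learns the 16S-to-WGS mapping from a paired training cohort and
then scores unseen 16S samples.

## The model

Abundances are worked with as `log_cpm = log10(1e6 * fraction + 1)`. Both
prediction modules are the linear mixed model

    y = X b + Z u + e,    u ~ N(0, Sigma),    e ~ N(0, sigma^2 I)

over the flattened species-by-sample WGS matrix, where `Z u` gives every
species its own random intercept (`Sigma = sigma_u^2 I` by default, or
`sigma_u^2 K` for a fixed species-correlation kernel `K`). The modules differ
only in the fixed-effects design `X`:

* **update module** — species detected on both platforms; `X` = intercept,
  the species' own 16S log_cpm value, group, time point;
* **imputation module** — WGS-only species; the 16S value is replaced by the
  sample's top 10 principal components of the whole 16S profile (the same 10
  PCs for every imputed species of a sample).

Fitting is restricted maximum likelihood with `beta` and `sigma^2` profiled
out, leaving a one-dimensional search over `theta = sqrt(sigma_u^2/sigma^2)`
(the Cholesky scale of the random-effect covariance); BLUPs of the species
effects shrink per-species mean residuals. Fixed-effects-only linear
regression (`fitLR`) and the FE / RE / COV+RE ablation variants
(`fitVariant`) share the same two-module design for comparison, and
`evaluateMethod` reports pooled and per-sample Pearson r and RMSE.

## Worked example

Train on the synthetic benchmark cohort (200 paired samples; 30 shared, 40
WGS-only, 10 16S-only species), score the held-out 20% and evaluate:

```r
library(shotgunPredict)

co <- simulateCohort(generatorConfig(seed = 1))
split <- splitTrainTest(co$meta$sample_id, seed = 1)
keep <- function(t, ids) AbundanceTable(abundanceValues(t)[, ids],
                                        platformType(t), abundanceUnit(t))

model <- trainPredictor(keep(co$s16, split$train), keep(co$wgs, split$train),
                        co$meta)
model
#> TrainedPredictor [variant=FULL]
#>   update module:     30 species
#>   imputation module: 40 species
model@updateFit
#> FittedLMM [diagonal]: 4 fixed effects, 30 species
#>   sigma2_e = 0.263, sigma2_u = 0.6553 (theta = 1.578), REML logLik = -3705.9120

pred <- predict(model, keep(co$s16, split$test), co$meta)
pred
#> PredictionResult: 70 species x 40 samples (30 updated, 40 imputed)

evaluateMethod(pred, keep(co$wgs, split$test), method = "mixed model")
#> EvalReport [mixed model, scheme=split8020]
#>   pooled Pearson r = 0.7184, pooled RMSE = 1.0492 (log_cpm), 70 species
#>   per-sample r: mean 0.7243 over 40 samples (0 undefined)
```

The update module's fitted slope on the 16S value sits near the generative
0.8, the species variance `sigma2_u` reflects the simulated platform offsets,
and the held-out pooled correlation of ~0.72 beats the fixed-effects-only
baseline (~0.55 on the same splits) because the random intercepts absorb the
per-species platform shifts.

Real tables are read with `readAbundanceTable(path, platform, dialect)`
(dialects: `plain_tsv`, `metaphlan`, `qiime2_tsv`) and
`readSampleMetadata(path)`; trained models serialize to a versioned JSON
bundle via `saveModelBundle()` / `readModelBundle()`. A thin command-line
wrapper with `simulate` / `train` / `predict` / `evaluate` subcommands ships
in `inst/scripts/shotgun-predict-cli.R`.

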