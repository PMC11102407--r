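---
title: "Predicting shotgun-comparable species profiles from 16S amplicon data"
author: "shotgunPredict"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting shotgun-comparable species profiles from 16S amplicon data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shotgunPredict)
```

## The problem

16S rRNA amplicon sequencing is cheap and ubiquitous but resolves microbial
communities coarsely and misses many species that whole-genome shotgun (WGS)
metagenomics detects. Paired profiling of the same stool samples on both
platforms shows a characteristic three-way split of species: a set detected by
**both** platforms (with systematically different abundance estimates), a large
set detected by **WGS only**, and a smaller set reported by **16S only**
(whose annotation is the least certain). `shotgunPredict` treats WGS as the
gold standard and predicts, from a 16S species table alone, the species-level
log-abundance profile that WGS would have produced — updating the
both-platform species and imputing the WGS-only ones.

## The model

All abundances are first put on a common working scale. 16S counts are
converted to relative fractions per sample, and every fraction $x$ is
transformed to

$$v = \log_{10}(10^6 x + 1),$$

so a zero count maps to 0 and typical detected species land between about 1
and 6. We call this scale log_cpm. WGS profilers already report relative
fractions, which go through the same log transform.

Both prediction modules are the same linear mixed model over the flattened
species-by-sample response,

$$y = X\beta + Zu + \varepsilon, \qquad
  u \sim \mathcal{N}(0, \Sigma), \quad
  \varepsilon \sim \mathcal{N}(0, \sigma^2 I_{nm}),$$

where $y$ stacks the WGS log_cpm values species-major ($n$ samples for each of
$m$ species), $Z$ is the per-species indicator so $u$ is a vector of
species-specific intercepts, and the modules differ only in $X$:

* **Update module** (species on both platforms): $X$ holds an intercept, the
  matched 16S log_cpm value of the same species in the same sample, and the
  two sample covariates (binary group, integer time point).
* **Imputation module** (WGS-only species): the 16S value is replaced by the
  sample's top $k = 10$ principal components of the full 16S log_cpm profile;
  the same PC values repeat for every imputed species of a sample, so the PCs
  act as a sample fingerprint from which each species' abundance is predicted
  through shared coefficients plus its own random intercept.

The fixed effects capture sample-specific information, the random intercepts
capture species-specific platform shifts, and the covariance $\Sigma$ of the
random effects can encode cross-species dependence.

### The covariance of the species effects

A single response vector of species intercepts cannot identify an
unstructured $m \times m$ covariance. The package therefore exposes two
covariance modes through the Cholesky-style scale parameter
$\theta = \sqrt{\sigma_u^2 / \sigma^2}$, so that
$\Sigma = \sigma^2 \Lambda_\theta \Lambda_\theta^\top$:

* `diagonal` (default): $\Sigma = \sigma_u^2 I$ — independent species
  intercepts, the structure a standard single-grouping mixed-model fit
  imposes;
* `kernel`: $\Sigma = \sigma_u^2 K$ for a user-supplied fixed positive
  semidefinite species-correlation matrix $K$ (for example an empirical
  co-abundance correlation, or a phylogenetically derived kernel), with one
  free scale parameter.

The two modes bracket the plausible interpretations of "correlations between
species" while keeping the model identifiable.

### Estimation

`remlFit()` maximizes the restricted likelihood with $\beta$ and $\sigma^2$
profiled out analytically, leaving a one-dimensional criterion in $\theta$:

$$\ell_R(\theta) = -\tfrac12\left[(N - p)\bigl(\log 2\pi\hat\sigma^2 + 1\bigr)
  + \log|W| + \log|X^\top W^{-1} X|\right],
  \qquad W = I + \theta^2 Z K Z^\top.$$

The Woodbury identity reduces every term to $m \times m$ linear algebra
($Z^\top v$ is a per-species row sum), so a fit on the default benchmark
(6,000 rows) takes well under a second. The criterion is maximized by a
deterministic coarse log-grid over $\theta \in [0, 100]$ followed by
golden-section refinement to a $10^{-8}$ tolerance; there are no random
starts, so fits are exactly reproducible. The boundary $\theta = 0$ (no
species effect) is evaluated explicitly and estimates are pinned there when
it is not beaten — in that case fixed effects equal ordinary least squares.
BLUPs are recovered as $\hat u = \theta^2 K Z^\top W^{-1}(y - X\hat\beta)$;
with balanced data and diagonal covariance this is the familiar shrinkage of
per-species mean residuals by $n\theta^2 / (1 + n\theta^2)$. A unit test
cross-checks fixed effects, variance components, BLUPs and the restricted
log-likelihood against `lme4::lmer` to $10^{-5}$, and the acceptance suite
checks the whole path against an independent dense brute-force oracle on 25
random small instances.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `pseudocount` | 1 | added after the $10^6$ scaling, before $\log_{10}$ |
| `scale` | $10^6$ | fraction-to-"counts per million" multiplier |
| `pcaK` | 10 | 16S principal components used by the imputation module |
| `minPrevalence` | 1 | samples with abundance $> 0$ needed to call a species "detected" on a platform |
| `covMode` | `"diagonal"` | covariance structure of the species random effects |
| `thetaMax`, `tol` | 100, $10^{-8}$ | REML search interval and convergence tolerance on $\theta$ |

Design choices made where the problem was genuinely open:

* **Detection rule.** "Detected on a platform" means non-zero abundance in at
  least one training sample — the weakest rule consistent with partitioning a
  paired cohort into both / WGS-only / 16S-only sets; `minPrevalence` makes it
  stricter when desired.
* **Species-name harmonization.** SILVA-style and MetaPhlAn-style lineages are
  reduced to canonical `"Genus species"` keys (underscores to spaces,
  bracketed genus markers stripped, genus capitalized, strain suffixes
  dropped). Cross-platform matching is exact on these keys.
* **Intercept.** A global intercept is always included even though the module
  descriptions count only the substantive covariates; the species random
  effects are centered at zero, so the intercept is required for the BLUPs to
  be orthogonal to the mean.
* **PCA convention.** PCs are computed on log_cpm values with per-species mean
  centering and no unit-variance scaling, and loading signs are fixed so each
  column's largest-magnitude entry is positive — runs are bit-reproducible.
* **Scoring conventions.** A both-platform species absent from a new sample's
  16S table is scored with a 16S log_cpm of 0 (the transform of a zero count)
  rather than dropped, so the output table is always complete. 16S-only
  species are excluded from the default output (WGS is the reference and
  never reports them); `passthroughS16Only = TRUE` appends them verbatim.
  Metadata columns missing at scoring time default to 0 with a warning — the
  ablation shows the covariates carry almost no signal.
* **Discordant species.** In a multi-cohort model, a species detected on both
  platforms in one cohort but WGS-only in another is fitted in both modules
  and scored by their unweighted mean.

## The baselines and the ablation

`fitLR()` fits the identical two-module design by ordinary least squares —
the fixed-effects-only comparator. `fitVariant()` exposes the component
ablation: `FULL` (everything), `FE` (no random effects, identical to the
linear-regression baseline), `RE` (intercept + species random effects only)
and `COV_RE` (metadata + random effects, no 16S value / PCs). All variants
share the preprocessing and scoring path, so held-out comparisons isolate the
model components.

## What the synthetic generator emulates

`simulateCohort()` draws paired tables with the structure the model assumes:

* per-sample latent factors drive the 16S composition through species
  loadings, so the 16S PCs genuinely summarize the sample;
* for shared species, WGS log_cpm is
  `slope * (16S log_cpm) + species offset + metadata effects + noise`, with
  offsets drawn $\mathcal{N}(0, \sigma_u^2 C)$ (optionally correlated);
* WGS-only species are driven by the same latent factors through their own
  loadings, so the imputation target is learnable exactly when the 16S PCs
  carry signal (setting `pcSignalSd = 0` removes all information and bounds
  the module honestly);
* the 16S table is emitted as absolute counts (fractions times a 50,000-read
  library, rounded), so the full normalization chain — relative abundance,
  log transform, detection-based partitioning — is exercised downstream, and
  rounding noise is part of the emitted data.

Two design points deserve emphasis. First, compositional closure: a column of
relative fractions must sum to one, so any mass given to platform-exclusive
species is taken from the shared ones. The generator fixes the total mass of
the 16S-only block per sample (default 15%) and lets the WGS-only block fill
the column's leftover mass, so closure does not leak sample-specific shifts
into the shared species; the structural relation above is inverted exactly
into the emitted WGS fractions via $x = (10^w - 1)/10^6$, with a single
cohort-wide constant (absorbed by the model intercept) calibrating the
shared-block mass. Second, censoring: a fraction cannot be negative, so
structural log_cpm values below zero are floored — together with count
rounding of rare species this makes the emitted tables realistically *harder*
than the idealized linear model. The generator therefore also records its
structural (pre-closure) WGS log_cpm and pre-rounding 16S log_cpm in `truth`;
parameter-recovery checks fit on those model-level values, while the
end-to-end accuracy and ranking checks run on the emitted tables, censoring
and all.

What passing tests do **not** show about real data: the generator draws
Gaussian factors and log-normal compositions with a stable block structure; it
has no batch effects, no phylogenetic signal beyond an optional correlation
kernel, no sequencing-depth variation, no taxonomy mis-annotation, and far
fewer zeros than real 16S tables. Synthetic benchmarks validate the
machinery and the qualitative component ordering, not field performance.

## Benchmark conditions used by the test suite

The standard benchmark scenario (the generator defaults) is 200 samples with
30 shared, 40 WGS-only and 10 16S-only species, slope 0.8, species-offset sd
1.0 and residual sd 0.5 (log_cpm units), metadata effects 0.3 (group) and 0.1
(per time point). The acceptance suite runs 20 seeds of this scenario for
parameter recovery and for the variant ranking (80:20 held-out splits), 20
seeds with silent metadata for the covariate ablation, a 60-sample zero-noise
zero-bias cohort for the identity limit, and 25 random small instances
(n ≤ 8, m ≤ 5) against the dense REML oracle. These sizes keep a full run
of the suite around a minute while leaving the statistical assertions
well-powered.

One acceptance note: with 30 species, the realized variance of the drawn
offsets has about 26% sampling error around $\sigma_u^2$, so variance-ratio
recovery is asserted against the realized centered offset variance (the
estimable quantity) rather than the population value; measured median
relative error is about 2%.

## Known limitations

* Only species present in a training cohort can ever be predicted; scoring a
  cohort with disjoint taxa yields an empty update table.
* Predictions are abundances, not sequences — no functional (gene or pathway)
  profiling can follow.
* Accuracy degrades under train/test heterogeneity (different populations,
  extraction kits, profiler versions); the cross-cohort evaluation scheme
  exists precisely to quantify that.
* The log-scale linear link is an approximation; strongly non-linear platform
  bias for individual taxa lands in the residual.

## A worked run

```{r example, eval = FALSE}
co <- simulateCohort(generatorConfig(seed = 1))
split <- splitTrainTest(co$meta$sample_id, seed = 1)
keep <- function(t, ids) AbundanceTable(abundanceValues(t)[, ids],
                                        platformType(t), abundanceUnit(t))
model <- trainPredictor(keep(co$s16, split$train), keep(co$wgs, split$train),
                        co$meta)
pred <- predict(model, keep(co$s16, split$test), co$meta)
evaluateMethod(pred, keep(co$wgs, split$test), method = "mixed model")
```
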