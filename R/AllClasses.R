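#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#' @importFrom S4Vectors metadata
#' @importFrom stats cor optimize rnorm rbinom runif sd median quantile setNames lm.fit chol2inv
#' @importFrom utils read.delim write.table head
NULL

.PLATFORMS <- c("S16", "WGS")
.UNITS <- c("absolute_count", "relative_fraction", "log_cpm")

#' AbundanceTable: a species-by-sample abundance matrix
#'
#' An `AbundanceTable` is a [SummarizedExperiment::SummarizedExperiment]
#' carrying a single `abundance` assay (rows = species, columns = samples)
#' together with the sequencing platform that produced it (`"S16"` for 16S
#' amplicon, `"WGS"` for shotgun) and the unit the values are expressed in:
#' `"absolute_count"` (non-negative counts), `"relative_fraction"` (columns sum
#' to 1), or `"log_cpm"` (`log10(1e6 * fraction + 1)`, the model's working
#' scale).
#'
#' Row names are canonical species keys (`"Genus species"`, see
#' [canonicalSpeciesKey()]); column names are sample identifiers. Both must be
#' unique. Values must be finite, and non-negative for count/fraction units;
#' relative-fraction columns must each sum to 1 within 1e-6.
#'
#' @slot platform character, one of `"S16"`, `"WGS"`.
#' @slot unit character, one of `"absolute_count"`, `"relative_fraction"`,
#'   `"log_cpm"`.
#'
#' @seealso [readAbundanceTable()], [toRelative()], [logCPM()]
#' @export
setClass("AbundanceTable",
  contains = "SummarizedExperiment",
  representation(platform = "character", unit = "character")
)

setValidity("AbundanceTable", function(object) {
  msg <- character()
  if (length(object@platform) != 1L || !object@platform %in% .PLATFORMS)
    msg <- c(msg, sprintf("platform must be one of %s", paste(.PLATFORMS, collapse = ", ")))
  if (length(object@unit) != 1L || !object@unit %in% .UNITS)
    msg <- c(msg, sprintf("unit must be one of %s", paste(.UNITS, collapse = ", ")))
  if (!"abundance" %in% SummarizedExperiment::assayNames(object))
    return(c(msg, "assay 'abundance' is required"))
  v <- SummarizedExperiment::assay(object, "abundance")
  if (is.null(rownames(v)) && nrow(v) > 0) msg <- c(msg, "species (row) names are required")
  if (is.null(colnames(v)) && ncol(v) > 0) msg <- c(msg, "sample (column) names are required")
  if (anyDuplicated(rownames(v))) msg <- c(msg, "duplicate species ids")
  if (anyDuplicated(colnames(v))) msg <- c(msg, "duplicate sample ids")
  if (length(v) && !all(is.finite(v))) msg <- c(msg, "all values must be finite")
  if (length(object@unit) == 1L && object@unit %in% c("absolute_count", "relative_fraction") &&
      length(v) && any(v < 0))
    msg <- c(msg, "negative values are not allowed for count/fraction units")
  if (identical(object@unit, "relative_fraction") && ncol(v) > 0 && nrow(v) > 0) {
    cs <- colSums(v)
    if (any(cs == 0)) msg <- c(msg, "all-zero sample columns are forbidden in relative_fraction unit")
    else if (any(abs(cs - 1) > 1e-6))
      msg <- c(msg, "relative_fraction columns must sum to 1 within 1e-6")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an AbundanceTable
#'
#' @param values numeric matrix, species in rows (row names = species keys),
#'   samples in columns (column names = sample ids).
#' @param platform `"S16"` or `"WGS"`.
#' @param unit `"absolute_count"`, `"relative_fraction"` or `"log_cpm"`.
#' @return An [AbundanceTable-class] object.
#' @examples
#' m <- matrix(c(2, 3, 5, 1, 0, 9), nrow = 3,
#'             dimnames = list(paste("Genus sp", 1:3), c("A", "B")))
#' AbundanceTable(m, platform = "S16", unit = "absolute_count")
#' @export
AbundanceTable <- function(values, platform = c("S16", "WGS"),
                           unit = c("absolute_count", "relative_fraction", "log_cpm")) {
  platform <- match.arg(platform)
  unit <- match.arg(unit)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  se <- SummarizedExperiment::SummarizedExperiment(assays = list(abundance = values))
  new("AbundanceTable", se, platform = platform, unit = unit)
}

#' SpeciesPartition: the three-way platform split of species
#'
#' Species in the union of a paired 16S/WGS cohort fall into exactly one of
#' three sets: detected on `both` platforms, `wgsOnly`, or `s16Only`. The sets
#' are pairwise disjoint and exhaustive for the union.
#'
#' @slot both character vector of species detected on both platforms.
#' @slot wgsOnly character vector of species detected by WGS only.
#' @slot s16Only character vector of species detected by 16S only.
#' @seealso [partitionSpecies()]
#' @export
setClass("SpeciesPartition",
  representation(both = "character", wgsOnly = "character", s16Only = "character")
)

setValidity("SpeciesPartition", function(object) {
  sets <- list(object@both, object@wgsOnly, object@s16Only)
  all_sp <- unlist(sets)
  if (anyDuplicated(all_sp)) return("partition sets must be pairwise disjoint")
  TRUE
})

#' PCFeatures: principal-component features of a 16S profile
#'
#' Principal components of the samples-by-species log_cpm matrix after
#' per-species mean centering (no scaling). Used as sample-level fixed-effect
#' covariates by the imputation module. If the data support fewer than `k`
#' components, the remaining score/loading columns are zero-padded. Loading
#' signs are fixed so each column's largest-magnitude entry is positive.
#'
#' @slot scores samples-by-k score matrix.
#' @slot loadings species-by-k loading matrix (orthonormal columns where
#'   non-degenerate).
#' @slot center named per-species mean vector used for centering.
#' @slot varExplained variance explained by each component (non-increasing).
#' @seealso [fitPCs()], [projectPCs()]
#' @export
setClass("PCFeatures",
  representation(scores = "matrix", loadings = "matrix",
                 center = "numeric", varExplained = "numeric")
)

setValidity("PCFeatures", function(object) {
  if (ncol(object@scores) != ncol(object@loadings)) return("scores/loadings k mismatch")
  if (nrow(object@loadings) != length(object@center)) return("loadings/center species mismatch")
  TRUE
})

#' MixedModelSpec: the design of one mixed-model module
#'
#' Holds the flattened response `y` (species-major: all samples of species 1,
#' then species 2, ...), the fixed-effects design `X` (with intercept), and the
#' species grouping that defines the random-intercept design `Z` (one indicator
#' column per species; materialized on demand by [designZ()]). `covMode`
#' selects the random-effect covariance: `"diagonal"` (Sigma = sigma_u^2 I) or
#' `"kernel"` (Sigma = sigma_u^2 K for a fixed PSD species correlation K).
#'
#' @slot y numeric response vector (WGS log_cpm).
#' @slot X fixed-effects design matrix, full column rank, first column intercept.
#' @slot species factor of length `length(y)` mapping rows to species.
#' @slot samples character vector of length `length(y)` mapping rows to samples.
#' @slot covMode `"diagonal"` or `"kernel"`.
#' @slot K species correlation matrix (kernel mode) or 0x0 matrix.
#' @seealso [buildDesign()], [remlFit()]
#' @export
setClass("MixedModelSpec",
  representation(y = "numeric", X = "matrix", species = "factor",
                 samples = "character", covMode = "character", K = "matrix")
)

setValidity("MixedModelSpec", function(object) {
  msg <- character()
  n <- length(object@y)
  if (nrow(object@X) != n) msg <- c(msg, "y and X row counts differ")
  if (length(object@species) != n) msg <- c(msg, "species index length mismatch")
  if (length(object@samples) != n) msg <- c(msg, "sample index length mismatch")
  if (!object@covMode %in% c("diagonal", "kernel")) msg <- c(msg, "covMode must be diagonal or kernel")
  if (object@covMode == "kernel") {
    m <- nlevels(object@species)
    if (!all(dim(object@K) == c(m, m))) msg <- c(msg, "K must be m x m")
    else if (max(abs(object@K - t(object@K))) > 1e-8) msg <- c(msg, "K must be symmetric")
  }
  if (length(msg)) msg else TRUE
})

#' FittedLMM: a fitted linear mixed model
#'
#' The result of [remlFit()] (or [fitLR()], which yields the theta = 0 special
#' case): BLUE fixed effects `beta`, BLUP per-species random intercepts `uHat`,
#' variance components, and the profiled REML log-likelihood at the optimum.
#'
#' @slot beta named fixed-effect estimates (BLUE).
#' @slot uHat named per-species random-effect predictions (BLUP).
#' @slot sigma2e residual variance.
#' @slot sigma2u random-effect variance scale (sigma_u^2).
#' @slot theta sqrt(sigma2u / sigma2e), the optimized scale parameter.
#' @slot remlLogLik profiled REML log-likelihood at the optimum.
#' @slot converged logical convergence flag.
#' @slot covMode `"diagonal"`, `"kernel"`, or `"none"` (OLS fit).
#' @slot K kernel matrix used (0x0 unless kernel mode).
#' @slot vcovBeta covariance matrix of beta (for standard errors).
#' @export
setClass("FittedLMM",
  representation(beta = "numeric", uHat = "numeric", sigma2e = "numeric",
                 sigma2u = "numeric", theta = "numeric", remlLogLik = "numeric",
                 converged = "logical", covMode = "character", K = "matrix",
                 vcovBeta = "matrix")
)

#' TrainedPredictor: a trained two-module 16S-to-WGS predictor
#'
#' Bundles the fitted update module (species on both platforms), the fitted
#' imputation module (WGS-only species), the PCA state of the training 16S
#' profile, the species partition, and the preprocessing configuration needed
#' to score a new 16S table reproducibly.
#'
#' @slot updateFit [FittedLMM-class] for the update module (may be empty).
#' @slot imputeFit [FittedLMM-class] for the imputation module (may be empty).
#' @slot pca [PCFeatures-class] fitted on the training 16S log_cpm table.
#' @slot partition [SpeciesPartition-class] of the training cohort.
#' @slot discordant species fitted in both modules (multi-cohort training);
#'   scored by averaging the two modules.
#' @slot variant model variant: `"FULL"`, `"FE"`, `"RE"` or `"COV_RE"`.
#' @slot config list: preprocessing and design settings snapshot.
#' @seealso [trainPredictor()], [trainMulticohort()], [fitVariant()]
#' @export
setClass("TrainedPredictor",
  representation(updateFit = "FittedLMM", imputeFit = "FittedLMM",
                 pca = "PCFeatures", partition = "SpeciesPartition",
                 discordant = "character", variant = "character", config = "list")
)

#' PredictionResult: a scored 16S cohort
#'
#' A log_cpm [AbundanceTable-class] over the predictable species (both-platform
#' union WGS-only) plus a per-species provenance tag: `"updated"` (update
#' module), `"imputed"` (imputation module), `"averaged"` (mean of both, for
#' species assigned discordantly across training cohorts), or `"passthrough"`
#' (16S-only species appended verbatim on request).
#'
#' @slot table predicted log_cpm [AbundanceTable-class].
#' @slot provenance named character, one tag per output species.
#' @export
setClass("PredictionResult",
  representation(table = "AbundanceTable", provenance = "character")
)

setValidity("PredictionResult", function(object) {
  sp <- rownames(object@table)
  if (!identical(sort(names(object@provenance)), sort(sp)))
    return("every output species must carry exactly one provenance tag")
  if (!all(object@provenance %in% c("updated", "imputed", "averaged", "passthrough")))
    return("unknown provenance tag")
  TRUE
})

#' EvalReport: accuracy report for one method on one evaluation scheme
#'
#' @slot method method name.
#' @slot scheme `"split8020"`, `"cross_cohort"` or `"independent"`.
#' @slot pooledPearson Pearson r over all (sample, species) cells.
#' @slot pooledRMSE RMSE over all cells, log_cpm units.
#' @slot perSample data.frame: sample_id, r, rmse (r is NA when undefined).
#' @slot perSpecies data.frame: species_id, r, rmse (extension, not pooled).
#' @slot nSpeciesEvaluated number of overlapping species evaluated.
#' @seealso [evaluateMethod()]
#' @export
setClass("EvalReport",
  representation(method = "character", scheme = "character",
                 pooledPearson = "numeric", pooledRMSE = "numeric",
                 perSample = "data.frame", perSpecies = "data.frame",
                 nSpeciesEvaluated = "integer")
)
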