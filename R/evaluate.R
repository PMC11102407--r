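#' Pearson product-moment correlation
#'
#' Standard Pearson correlation between predicted and true values. Constant
#' input vectors have no defined correlation and raise an error; evaluation
#' harnesses report such cases as missing (`NA`), never as 0.
#'
#' @param pred,truth numeric vectors of equal length (>= 2).
#' @return correlation coefficient in \[-1, 1\].
#' @export
pearsonR <- function(pred, truth) {
  stopifnot(length(pred) == length(truth), length(pred) >= 2)
  if (sd(pred) == 0 || sd(truth) == 0)
    stop("undefined correlation: constant input vector")
  cor(pred, truth)
}

.safePearson <- function(pred, truth) {
  if (length(pred) < 2 || sd(pred) == 0 || sd(truth) == 0) return(NA_real_)
  cor(pred, truth)
}

#' Root mean square error
#'
#' @param pred,truth numeric vectors of equal length.
#' @return `sqrt(mean((pred - truth)^2))`.
#' @export
rmse <- function(pred, truth) {
  stopifnot(length(pred) == length(truth), length(pred) >= 1)
  sqrt(mean((pred - truth)^2))
}

#' Deterministic 80:20 train/test split
#'
#' Splits sample ids into disjoint, exhaustive train and test sets with
#' `round(testFraction * n)` test samples, deterministically for a given
#' seed. The caller's RNG state is left untouched.
#'
#' @param samples character vector of sample ids (>= 5).
#' @param seed integer seed.
#' @param testFraction fraction held out (default 0.2).
#' @return list with `train` and `test` character vectors.
#' @export
splitTrainTest <- function(samples, seed, testFraction = 0.2) {
  n <- length(samples)
  if (n < 5) stop("at least 5 samples are required for a split")
  n_test <- max(1L, min(n - 1L, round(testFraction * n)))
  test <- withLocalSeed(seed, sample(samples, n_test))
  list(train = setdiff(samples, test), test = sort(test))
}

#' Evaluate predictions against a truth table
#'
#' Restricts to the species and samples present in both the predictions and
#' the truth table (an error if no species overlap), then computes pooled
#' Pearson/RMSE over all (sample, species) cells, per-sample metrics over each
#' sample's species vector, and per-species metrics (an extension beyond the
#' per-dataset/per-sample convention). Samples whose vectors are constant get
#' `NA` correlation.
#'
#' @param predictions a [PredictionResult-class] or a `log_cpm`
#'   [AbundanceTable-class].
#' @param truth the true WGS [AbundanceTable-class] (normalized to log_cpm if
#'   needed).
#' @param method method label for the report.
#' @param scheme `"split8020"`, `"cross_cohort"` or `"independent"`.
#' @return An [EvalReport-class].
#' @export
evaluateMethod <- function(predictions, truth, method = "method",
                           scheme = c("split8020", "cross_cohort", "independent")) {
  scheme <- match.arg(scheme)
  pt <- if (is(predictions, "PredictionResult")) predictions@table else predictions
  stopifnot(is(pt, "AbundanceTable"), is(truth, "AbundanceTable"))
  truth <- normalizeToLogCPM(truth)
  species <- intersect(speciesIds(pt), speciesIds(truth))
  if (!length(species)) stop("zero overlapping species between predictions and truth")
  samples <- intersect(sampleIds(pt), sampleIds(truth))
  if (!length(samples)) stop("no shared samples between predictions and truth")
  P <- abundanceValues(pt)[species, samples, drop = FALSE]
  Tm <- abundanceValues(truth)[species, samples, drop = FALSE]
  per_sample <- data.frame(
    sample_id = samples,
    r = vapply(samples, function(s) .safePearson(P[, s], Tm[, s]), numeric(1)),
    rmse = vapply(samples, function(s) rmse(P[, s], Tm[, s]), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  per_species <- data.frame(
    species_id = species,
    r = vapply(species, function(s) .safePearson(P[s, ], Tm[s, ]), numeric(1)),
    rmse = vapply(species, function(s) rmse(P[s, ], Tm[s, ]), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  new("EvalReport", method = method, scheme = scheme,
      pooledPearson = .safePearson(as.vector(P), as.vector(Tm)),
      pooledRMSE = rmse(as.vector(P), as.vector(Tm)),
      perSample = per_sample, perSpecies = per_species,
      nSpeciesEvaluated = length(species))
}

#' Benchmark model variants on one synthetic cohort
#'
#' Trains each requested variant on the training samples of an 80:20 split,
#' scores the held-out samples, and evaluates against the held-out WGS truth.
#'
#' @param cohort a cohort list from [simulateCohort()].
#' @param variants character vector of variants (see [modelVariant()]).
#' @param seed split seed.
#' @param testFraction held-out fraction (default 0.2).
#' @param pcaK PCs for the imputation module (default 10).
#' @return data.frame: variant, pooled_r, pooled_rmse, mean_sample_r.
#' @export
benchmarkVariants <- function(cohort, variants = c("FE", "RE", "COV_RE", "FULL"),
                              seed = 1, testFraction = 0.2, pcaK = 10) {
  split <- splitTrainTest(sampleIds(cohort$s16), seed, testFraction)
  sub <- function(t, ids) {
    AbundanceTable(abundanceValues(t)[, ids, drop = FALSE],
                   platform = platformType(t), unit = abundanceUnit(t))
  }
  s16_tr <- sub(cohort$s16, split$train); s16_te <- sub(cohort$s16, split$test)
  wgs_tr <- sub(cohort$wgs, split$train); wgs_te <- sub(cohort$wgs, split$test)
  meta <- cohort$meta
  res <- lapply(variants, function(v) {
    fit <- fitVariant(v, s16_tr, wgs_tr, meta, pcaK = pcaK)
    pr <- predict(fit, s16_te, meta)
    report <- evaluateMethod(pr, wgs_te, method = v)
    data.frame(variant = v, pooled_r = report@pooledPearson,
               pooled_rmse = report@pooledRMSE,
               mean_sample_r = mean(report@perSample$r, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
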