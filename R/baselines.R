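#' Ordinary least squares fit of a mixed-model design
#'
#' The fixed-effects-only comparator: fits `y = X beta + e` by OLS on the same
#' design as [remlFit()], ignoring the random-effects term. Returned as a
#' [FittedLMM-class] with `theta = 0` and zero BLUPs so that prediction and
#' downstream scoring are identical in structure to the mixed model.
#'
#' @param spec a [MixedModelSpec-class].
#' @return A [FittedLMM-class] with `covMode = "none"`.
#' @export
fitLR <- function(spec) {
  stopifnot(is(spec, "MixedModelSpec"))
  X <- spec@X; y <- spec@y
  fit <- lm.fit(X, y)
  if (fit$rank < ncol(X)) stop("fixed-effects design X is rank deficient")
  beta <- setNames(fit$coefficients, colnames(X))
  N <- length(y); p <- ncol(X)
  sigma2 <- sum(fit$residuals^2) / (N - p)
  XtXinv <- chol2inv(chol(crossprod(X)))
  new("FittedLMM",
      beta = beta,
      uHat = setNames(rep(0, nlevels(spec@species)), levels(spec@species)),
      sigma2e = sigma2, sigma2u = 0, theta = 0,
      remlLogLik = -0.5 * ((N - p) * (log(2 * pi * sigma2) + 1) +
                             as.numeric(determinant(crossprod(X), logarithm = TRUE)$modulus)),
      converged = TRUE, covMode = "none", K = matrix(0, 0, 0),
      vcovBeta = sigma2 * XtXinv)
}

.VARIANTS <- c("FULL", "FE", "RE", "COV_RE")

#' Model-variant flags for the component ablation
#'
#' The four submodels of the component dissection: `FULL` (sample covariate +
#' metadata + random effects — the complete method), `FE` (fixed effects only;
#' identical to the linear-regression baseline), `RE` (intercept + species
#' random effects only), and `COV_RE` (metadata + random effects, the 16S/PC
#' sample covariate removed).
#'
#' @param name one of `"FULL"`, `"FE"`, `"RE"`, `"COV_RE"`.
#' @return list of flags: `includeSampleCovariate`, `includeMetadata`,
#'   `includeRandomEffects`.
#' @export
modelVariant <- function(name = .VARIANTS) {
  name <- match.arg(name)
  switch(name,
    FULL = list(includeSampleCovariate = TRUE, includeMetadata = TRUE,
                includeRandomEffects = TRUE),
    FE = list(includeSampleCovariate = TRUE, includeMetadata = TRUE,
              includeRandomEffects = FALSE),
    RE = list(includeSampleCovariate = FALSE, includeMetadata = FALSE,
              includeRandomEffects = TRUE),
    COV_RE = list(includeSampleCovariate = FALSE, includeMetadata = TRUE,
                  includeRandomEffects = TRUE))
}

#' Train an ablation variant of the two-module predictor
#'
#' Same training pipeline and preprocessing as [trainPredictor()], with
#' design-matrix components included or excluded per the variant flags. The
#' `FULL` variant is identical to [trainPredictor()]; `FE` is the
#' linear-regression baseline ([fitLR()] in both modules).
#'
#' @param variant one of `"FULL"`, `"FE"`, `"RE"`, `"COV_RE"`.
#' @inheritParams trainPredictor
#' @return A [TrainedPredictor-class].
#' @export
fitVariant <- function(variant, s16, wgs, meta, pcaK = 10, minPrevalence = 1,
                       covMode = "diagonal", K = NULL) {
  variant <- match.arg(variant, .VARIANTS)
  trainPredictor(s16, wgs, meta, pcaK = pcaK, minPrevalence = minPrevalence,
                 covMode = covMode, K = K, variant = variant)
}
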