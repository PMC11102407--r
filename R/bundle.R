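.BUNDLE_SCHEMA <- "shotgunPredict-bundle/1"

.fitToList <- function(fit) {
  list(beta = as.list(fit@beta), uHat = as.list(fit@uHat),
       sigma2e = fit@sigma2e, sigma2u = fit@sigma2u, theta = fit@theta,
       remlLogLik = fit@remlLogLik, converged = fit@converged,
       covMode = fit@covMode,
       K = if (length(fit@K)) list(values = as.vector(fit@K), dim = dim(fit@K)) else NULL,
       vcovBeta = list(values = as.vector(fit@vcovBeta), dim = dim(fit@vcovBeta)))
}

.listToFit <- function(x) {
  if (!length(x$beta)) return(.emptyFit())
  K <- if (is.null(x$K)) matrix(0, 0, 0) else
    matrix(as.numeric(unlist(x$K$values)), unlist(x$K$dim)[1], unlist(x$K$dim)[2])
  new("FittedLMM",
      beta = unlist(x$beta), uHat = unlist(x$uHat),
      sigma2e = x$sigma2e, sigma2u = x$sigma2u, theta = x$theta,
      remlLogLik = x$remlLogLik, converged = x$converged, covMode = x$covMode,
      K = K, vcovBeta = matrix(as.numeric(unlist(x$vcovBeta$values)),
                               unlist(x$vcovBeta$dim)[1], unlist(x$vcovBeta$dim)[2]))
}

.matToList <- function(m) list(values = as.vector(m), dim = dim(m),
                               rownames = rownames(m), colnames = colnames(m))
.listToMat <- function(x) {
  dm <- as.integer(unlist(x$dim))
  m <- matrix(as.numeric(unlist(x$values) %||% numeric(0)), dm[1], dm[2])
  dimnames(m) <- list(unlist(x$rownames), unlist(x$colnames))
  m
}

#' Save a trained predictor bundle as JSON
#'
#' Serializes a [TrainedPredictor-class] — both fitted modules, the PCA state,
#' the species partition and the preprocessing configuration — to a single
#' versioned JSON file that [readModelBundle()] restores exactly.
#'
#' @param predictor a [TrainedPredictor-class].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
saveModelBundle <- function(predictor, path) {
  stopifnot(is(predictor, "TrainedPredictor"))
  obj <- list(
    schema = .BUNDLE_SCHEMA,
    variant = predictor@variant,
    updateFit = .fitToList(predictor@updateFit),
    imputeFit = .fitToList(predictor@imputeFit),
    pca = list(scores = .matToList(predictor@pca@scores),
               loadings = .matToList(predictor@pca@loadings),
               center = as.list(predictor@pca@center),
               varExplained = predictor@pca@varExplained),
    partition = list(both = predictor@partition@both,
                     wgsOnly = predictor@partition@wgsOnly,
                     s16Only = predictor@partition@s16Only),
    discordant = predictor@discordant,
    config = predictor@config)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Restore a trained predictor bundle
#'
#' @param path JSON file written by [saveModelBundle()].
#' @return A [TrainedPredictor-class].
#' @export
readModelBundle <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(x$schema, .BUNDLE_SCHEMA))
    stop("unrecognized bundle schema: ", x$schema %||% "<missing>")
  chr <- function(v) as.character(unlist(v) %||% character(0))
  cfg <- x$config
  cfg$flags <- lapply(cfg$flags, isTRUE)
  cfg$trainedSamples <- chr(cfg$trainedSamples)
  new("TrainedPredictor",
      updateFit = .listToFit(x$updateFit),
      imputeFit = .listToFit(x$imputeFit),
      pca = new("PCFeatures",
                scores = .listToMat(x$pca$scores),
                loadings = .listToMat(x$pca$loadings),
                center = unlist(x$pca$center),
                varExplained = as.numeric(unlist(x$pca$varExplained))),
      partition = new("SpeciesPartition", both = chr(x$partition$both),
                      wgsOnly = chr(x$partition$wgsOnly),
                      s16Only = chr(x$partition$s16Only)),
      discordant = chr(x$discordant), variant = x$variant,
      config = cfg)
}
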