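#' @rdname AbundanceTable-class
#' @export
setMethod("platformType", "AbundanceTable", function(x) x@platform)

#' @rdname AbundanceTable-class
#' @export
setMethod("abundanceUnit", "AbundanceTable", function(x) x@unit)

#' @rdname AbundanceTable-class
#' @export
setMethod("abundanceValues", "AbundanceTable", function(x)
  SummarizedExperiment::assay(x, "abundance"))

#' @rdname AbundanceTable-class
#' @export
setMethod("speciesIds", "AbundanceTable", function(x) rownames(x))

#' @rdname AbundanceTable-class
#' @export
setMethod("sampleIds", "AbundanceTable", function(x) colnames(x))

#' @rdname SpeciesPartition-class
#' @export
setMethod("bothSpecies", "SpeciesPartition", function(x) x@both)

#' @rdname SpeciesPartition-class
#' @export
setMethod("wgsOnlySpecies", "SpeciesPartition", function(x) x@wgsOnly)

#' @rdname SpeciesPartition-class
#' @export
setMethod("s16OnlySpecies", "SpeciesPartition", function(x) x@s16Only)

#' @rdname PredictionResult-class
#' @export
setMethod("predictedTable", "PredictionResult", function(x) x@table)

#' @rdname PredictionResult-class
#' @export
setMethod("provenance", "PredictionResult", function(x) x@provenance)

setMethod("show", "AbundanceTable", function(object) {
  cat(sprintf("AbundanceTable: %d species x %d samples [platform=%s, unit=%s]\n",
              nrow(object), ncol(object), object@platform, object@unit))
  if (nrow(object) > 0) {
    sp <- head(rownames(object), 3)
    cat("  species: ", paste(sp, collapse = ", "),
        if (nrow(object) > 3) ", ..." else "", "\n", sep = "")
  }
})

setMethod("show", "SpeciesPartition", function(object) {
  cat(sprintf("SpeciesPartition: %d both | %d WGS-only | %d 16S-only (union %d)\n",
              length(object@both), length(object@wgsOnly), length(object@s16Only),
              length(object@both) + length(object@wgsOnly) + length(object@s16Only)))
})

setMethod("show", "FittedLMM", function(object) {
  cat(sprintf("FittedLMM [%s]: %d fixed effects, %d species\n",
              object@covMode, length(object@beta), length(object@uHat)))
  cat(sprintf("  sigma2_e = %.4g, sigma2_u = %.4g (theta = %.4g), REML logLik = %.4f%s\n",
              object@sigma2e, object@sigma2u, object@theta, object@remlLogLik,
              if (object@converged) "" else "  [NOT CONVERGED]"))
})

setMethod("show", "TrainedPredictor", function(object) {
  cat(sprintf("TrainedPredictor [variant=%s]\n", object@variant))
  cat(sprintf("  update module:     %d species%s\n", length(object@updateFit@uHat),
              if (length(object@updateFit@uHat)) "" else " (skipped)"))
  cat(sprintf("  imputation module: %d species%s\n", length(object@imputeFit@uHat),
              if (length(object@imputeFit@uHat)) "" else " (skipped)"))
  if (length(object@discordant))
    cat(sprintf("  discordant (averaged): %d species\n", length(object@discordant)))
})

setMethod("show", "PredictionResult", function(object) {
  tab <- table(factor(object@provenance,
                      levels = c("updated", "imputed", "averaged", "passthrough")))
  cat(sprintf("PredictionResult: %d species x %d samples (%s)\n",
              nrow(object@table), ncol(object@table),
              paste(sprintf("%d %s", tab, names(tab))[tab > 0], collapse = ", ")))
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport [%s, scheme=%s]\n", object@method, object@scheme))
  cat(sprintf("  pooled Pearson r = %.4f, pooled RMSE = %.4f (log_cpm), %d species\n",
              object@pooledPearson, object@pooledRMSE, object@nSpeciesEvaluated))
  rr <- object@perSample$r
  cat(sprintf("  per-sample r: mean %.4f over %d samples (%d undefined)\n",
              mean(rr, na.rm = TRUE), nrow(object@perSample), sum(is.na(rr))))
})
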