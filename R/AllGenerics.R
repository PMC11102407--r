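#' @rdname AbundanceTable-class
#' @param x,object an object.
#' @export
setGeneric("platformType", function(x) standardGeneric("platformType"))

#' @rdname AbundanceTable-class
#' @export
setGeneric("abundanceUnit", function(x) standardGeneric("abundanceUnit"))

#' @rdname AbundanceTable-class
#' @export
setGeneric("abundanceValues", function(x) standardGeneric("abundanceValues"))

#' @rdname AbundanceTable-class
#' @export
setGeneric("speciesIds", function(x) standardGeneric("speciesIds"))

#' @rdname AbundanceTable-class
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' Convert absolute counts to relative fractions
#' @param x an [AbundanceTable-class] in `absolute_count` unit.
#' @return An [AbundanceTable-class] in `relative_fraction` unit.
#' @export
setGeneric("toRelative", function(x) standardGeneric("toRelative"))

#' Log-CPM normalization: log10(1e6 * fraction + 1)
#' @param x an [AbundanceTable-class] in `relative_fraction` unit.
#' @param scale multiplier applied before the log (default 1e6).
#' @param pseudocount value added before the log (default 1).
#' @return An [AbundanceTable-class] in `log_cpm` unit.
#' @export
setGeneric("logCPM", function(x, scale = 1e6, pseudocount = 1) standardGeneric("logCPM"))

#' @rdname SpeciesPartition-class
#' @param x a `SpeciesPartition`.
#' @export
setGeneric("bothSpecies", function(x) standardGeneric("bothSpecies"))

#' @rdname SpeciesPartition-class
#' @export
setGeneric("wgsOnlySpecies", function(x) standardGeneric("wgsOnlySpecies"))

#' @rdname SpeciesPartition-class
#' @export
setGeneric("s16OnlySpecies", function(x) standardGeneric("s16OnlySpecies"))

#' Best linear unbiased predictors of the species random effects
#' @param fit a [FittedLMM-class].
#' @return Named numeric vector of per-species BLUPs.
#' @export
setGeneric("blup", function(fit) standardGeneric("blup"))

#' Materialize the random-effects indicator design Z
#' @param spec a [MixedModelSpec-class].
#' @return The n-by-m 0/1 indicator matrix (one column per species).
#' @export
setGeneric("designZ", function(spec) standardGeneric("designZ"))

#' @rdname PredictionResult-class
#' @param x a `PredictionResult`.
#' @export
setGeneric("predictedTable", function(x) standardGeneric("predictedTable"))

#' @rdname PredictionResult-class
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
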