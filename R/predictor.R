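# Align a metadata data.frame to sample ids; missing samples are an error,
# missing group/timepoint columns default to 0 with a warning (the ablation
# shows metadata carries little signal, so scoring without it is permitted).
.alignMeta <- function(meta, sample_ids) {
  if (is.null(meta)) {
    warning("no metadata supplied; group and timepoint default to 0")
    return(data.frame(sample_id = sample_ids, group = 0, timepoint = 0,
                      row.names = sample_ids, stringsAsFactors = FALSE))
  }
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (!"sample_id" %in% colnames(meta)) stop("metadata needs a sample_id column")
  missing <- setdiff(sample_ids, meta$sample_id)
  if (length(missing))
    stop("metadata missing for sample(s): ", paste(missing, collapse = ", "))
  for (col in c("group", "timepoint")) {
    if (!col %in% colnames(meta)) {
      warning("metadata lacks '", col, "'; defaulting to 0")
      meta[[col]] <- 0
    }
  }
  rownames(meta) <- meta$sample_id
  out <- meta[sample_ids, c("sample_id", "group", "timepoint")]
  out$group <- as.numeric(out$group)
  out$timepoint <- as.numeric(out$timepoint)
  out
}

# Species-by-sample matrix of 16S log_cpm values for a species set; species
# absent from the table get log_cpm 0 (the transform of a zero count).
.s16ValueMatrix <- function(s16lc, species, sample_ids) {
  out <- matrix(0, length(species), length(sample_ids),
                dimnames = list(species, sample_ids))
  v <- abundanceValues(s16lc)
  shared <- intersect(species, rownames(v))
  out[shared, ] <- v[shared, sample_ids, drop = FALSE]
  out
}

.fitModule <- function(response, cellCovariates, sampleCovariates, flags,
                       covMode, K) {
  spec <- buildDesign(response,
                      cellCovariates = if (flags$includeSampleCovariate)
                        cellCovariates else list(),
                      sampleCovariates = sampleCovariates,
                      covMode = if (flags$includeRandomEffects) covMode else "diagonal",
                      K = if (flags$includeRandomEffects) K else NULL)
  if (flags$includeRandomEffects) remlFit(spec) else fitLR(spec)
}

.moduleSampleCovariates <- function(pcs, meta, flags, usePCs) {
  parts <- list()
  if (usePCs && flags$includeSampleCovariate) parts$pcs <- pcs
  if (flags$includeMetadata)
    parts$meta <- as.matrix(meta[, c("group", "timepoint"), drop = FALSE])
  if (!length(parts)) return(NULL)
  do.call(cbind, parts)
}

#' Train the two-module 16S-to-WGS predictor
#'
#' Trains the complete method on a paired cohort: the *update module* — a
#' linear mixed model over species detected on both platforms with fixed
#' effects (intercept, matched 16S log_cpm value, group, timepoint) and a
#' per-species random intercept — and the *imputation module* — the same
#' mixed model over WGS-only species with the sample's top-`pcaK` 16S
#' principal components replacing the matched 16S value (the same PC values
#' repeat for every imputed species of a sample). Both tables are normalized
#' to the log_cpm working scale first; the preprocessing state (PC loadings,
#' species lists, configuration) is stored in the returned bundle so unseen
#' samples are scored reproducibly.
#'
#' If a partition set is empty the corresponding module is skipped with a
#' warning and the bundle scores with the remaining module only.
#'
#' @param s16 16S [AbundanceTable-class] (any unit; counts are normalized).
#' @param wgs paired WGS [AbundanceTable-class] (same sample ids).
#' @param meta data.frame with columns sample_id, group, timepoint.
#' @param pcaK number of 16S principal components (default 10).
#' @param minPrevalence detection threshold for [partitionSpecies()].
#' @param covMode random-effect covariance: `"diagonal"` or `"kernel"`.
#' @param K species correlation matrix for kernel mode.
#' @param variant model variant (see [modelVariant()]); `"FULL"` is the
#'   complete method.
#' @return A [TrainedPredictor-class].
#' @export
trainPredictor <- function(s16, wgs, meta, pcaK = 10, minPrevalence = 1,
                           covMode = c("diagonal", "kernel"), K = NULL,
                           variant = "FULL") {
  covMode <- match.arg(covMode)
  variant <- match.arg(variant, .VARIANTS)
  flags <- modelVariant(variant)
  if (!setequal(sampleIds(s16), sampleIds(wgs))) {
    unpaired <- c(setdiff(sampleIds(s16), sampleIds(wgs)),
                  setdiff(sampleIds(wgs), sampleIds(s16)))
    stop("unpaired sample(s): ", paste(unpaired, collapse = ", "))
  }
  sample_ids <- sampleIds(s16)
  meta <- .alignMeta(meta, sample_ids)
  s16lc <- normalizeToLogCPM(s16)
  wgslc <- normalizeToLogCPM(wgs)
  wgsv <- abundanceValues(wgslc)[, sample_ids, drop = FALSE]
  part <- partitionSpecies(s16lc, wgslc, minPrevalence)
  pca <- fitPCs(s16lc, k = pcaK)
  updateFit <- .emptyFit(); imputeFit <- .emptyFit()
  if (length(part@both)) {
    resp <- wgsv[part@both, , drop = FALSE]
    s16m <- .s16ValueMatrix(s16lc, part@both, sample_ids)
    updateFit <- .fitModule(resp, list(s16 = s16m),
                            .moduleSampleCovariates(NULL, meta, flags, usePCs = FALSE),
                            flags, covMode, K)
  } else warning("no species detected on both platforms; update module skipped")
  if (length(part@wgsOnly)) {
    resp <- wgsv[part@wgsOnly, , drop = FALSE]
    pcs <- pca@scores[sample_ids, , drop = FALSE]
    imputeFit <- .fitModule(resp, list(),
                            .moduleSampleCovariates(pcs, meta, flags, usePCs = TRUE),
                            flags, covMode, K)
  } else warning("no WGS-only species; imputation module skipped")
  new("TrainedPredictor",
      updateFit = updateFit, imputeFit = imputeFit, pca = pca,
      partition = part, discordant = character(0), variant = variant,
      config = list(pcaK = pcaK, minPrevalence = minPrevalence,
                    covMode = covMode, scale = 1e6, pseudocount = 1,
                    flags = flags, trainedSamples = sample_ids))
}

# Predict one module for a species set; returns species x sample matrix.
.scoreModule <- function(fit, species, sample_ids, flags, s16cell = NULL,
                         pcs = NULL, meta) {
  cols <- list(`(Intercept)` = rep(1, length(species) * length(sample_ids)))
  if (flags$includeSampleCovariate) {
    if (!is.null(s16cell)) cols$s16 <- as.vector(t(s16cell[species, sample_ids, drop = FALSE]))
    if (!is.null(pcs)) {
      for (j in seq_len(ncol(pcs)))
        cols[[colnames(pcs)[j]]] <- rep(pcs[sample_ids, j], times = length(species))
    }
  }
  if (flags$includeMetadata) {
    cols$group <- rep(meta[sample_ids, "group"], times = length(species))
    cols$timepoint <- rep(meta[sample_ids, "timepoint"], times = length(species))
  }
  X <- do.call(cbind, cols)
  sp <- rep(species, each = length(sample_ids))
  yhat <- predict(fit, X, sp)
  matrix(yhat, nrow = length(species), byrow = TRUE,
         dimnames = list(species, sample_ids))
}

#' Score a new 16S cohort into a WGS-comparable table
#'
#' Applies a trained bundle to an unseen 16S table: species in the
#' both-platform set get the update-module prediction (species absent from the
#' new table are fed a 16S log_cpm of 0, the transform of a zero count);
#' WGS-only species get the imputation-module prediction from the projected
#' PCs; species assigned discordantly across training cohorts get the
#' unweighted mean of the two modules. 16S-only species are excluded unless
#' `passthroughS16Only = TRUE`, which appends their normalized values
#' verbatim with tag `"passthrough"`.
#'
#' @param object a [TrainedPredictor-class].
#' @param s16 new 16S [AbundanceTable-class] (normalized with the bundle's
#'   stored configuration, not re-derived).
#' @param meta data.frame with sample_id, group, timepoint for the new
#'   samples (optional columns default to 0 with a warning).
#' @param passthroughS16Only append 16S-only species unchanged (default
#'   FALSE).
#' @param ... ignored.
#' @return A [PredictionResult-class].
#' @export
setMethod("predict", "TrainedPredictor", function(object, s16, meta = NULL,
                                                  passthroughS16Only = FALSE, ...) {
  cfg <- object@config
  sample_ids <- sampleIds(s16)
  meta <- .alignMeta(meta, sample_ids)
  s16lc <- normalizeToLogCPM(s16, scale = cfg$scale, pseudocount = cfg$pseudocount)
  flags <- cfg$flags
  part <- object@partition
  upd_species <- c(part@both, object@discordant)
  imp_species <- c(part@wgsOnly, object@discordant)
  out_species <- c(part@both, part@wgsOnly, object@discordant)
  pred <- matrix(NA_real_, length(out_species), length(sample_ids),
                 dimnames = list(out_species, sample_ids))
  prov <- setNames(rep("updated", length(out_species)), out_species)
  prov[part@wgsOnly] <- "imputed"
  prov[object@discordant] <- "averaged"
  if (length(upd_species) && length(object@updateFit@uHat)) {
    s16cell <- .s16ValueMatrix(s16lc, upd_species, sample_ids)
    pred[upd_species, ] <- .scoreModule(object@updateFit, upd_species, sample_ids,
                                        flags, s16cell = s16cell, meta = meta)
  }
  if (length(imp_species) && length(object@imputeFit@uHat)) {
    pcs <- projectPCs(object@pca, s16lc)
    imp <- .scoreModule(object@imputeFit, imp_species, sample_ids, flags,
                        pcs = pcs, meta = meta)
    disc <- object@discordant
    pred[part@wgsOnly, ] <- imp[part@wgsOnly, , drop = FALSE]
    if (length(disc)) {
      upd_part <- pred[disc, , drop = FALSE]   # NA if the update module is absent
      avg <- (upd_part + imp[disc, , drop = FALSE]) / 2
      avg[is.na(upd_part)] <- imp[disc, , drop = FALSE][is.na(upd_part)]
      pred[disc, ] <- avg
    }
  }
  pred <- pred[!apply(is.na(pred), 1, all), , drop = FALSE]
  prov <- prov[rownames(pred)]
  if (passthroughS16Only && length(part@s16Only)) {
    extra <- .s16ValueMatrix(s16lc, part@s16Only, sample_ids)
    pred <- rbind(pred, extra)
    prov <- c(prov, setNames(rep("passthrough", length(part@s16Only)), part@s16Only))
  }
  new("PredictionResult",
      table = AbundanceTable(pred, platform = "WGS", unit = "log_cpm"),
      provenance = prov)
})

#' Train a multi-cohort predictor
#'
#' Pools two or more harmonized paired cohorts into one model. Partitions are
#' computed per cohort; species classified concordantly go to the
#' corresponding module, while species detected on both platforms in one
#' cohort but WGS-only in another ("discordant" species) are fitted in *both*
#' modules and scored by averaging the two modules' predictions. Species
#' tables are pooled after per-sample normalization with zero-fill for
#' species absent from a cohort.
#'
#' @param cohorts list of `list(s16 = , wgs = , meta = )`; sample ids must be
#'   disjoint across cohorts.
#' @inheritParams trainPredictor
#' @return A [TrainedPredictor-class] (with a non-empty `discordant` slot when
#'   assignments disagree across cohorts).
#' @export
trainMulticohort <- function(cohorts, pcaK = 10, minPrevalence = 1,
                             covMode = c("diagonal", "kernel"), K = NULL,
                             variant = "FULL") {
  covMode <- match.arg(covMode)
  variant <- match.arg(variant, .VARIANTS)
  flags <- modelVariant(variant)
  stopifnot(length(cohorts) >= 1)
  if (length(cohorts) == 1L)
    return(trainPredictor(cohorts[[1]]$s16, cohorts[[1]]$wgs, cohorts[[1]]$meta,
                          pcaK = pcaK, minPrevalence = minPrevalence,
                          covMode = covMode, K = K, variant = variant))
  all_samples <- unlist(lapply(cohorts, function(co) sampleIds(co$s16)))
  if (anyDuplicated(all_samples))
    stop("overlapping sample ids across cohorts: ",
         paste(unique(all_samples[duplicated(all_samples)]), collapse = ", "))
  norm <- lapply(cohorts, function(co) {
    s16lc <- normalizeToLogCPM(co$s16)
    wgslc <- normalizeToLogCPM(co$wgs)
    list(s16 = s16lc, wgs = wgslc,
         part = partitionSpecies(s16lc, wgslc, minPrevalence),
         meta = .alignMeta(co$meta, sampleIds(co$s16)))
  })
  in_both <- unique(unlist(lapply(norm, function(x) x$part@both)))
  in_wgs <- unique(unlist(lapply(norm, function(x) x$part@wgsOnly)))
  in_s16 <- unique(unlist(lapply(norm, function(x) x$part@s16Only)))
  discordant <- sort(intersect(in_both, in_wgs))
  upd <- sort(setdiff(in_both, discordant))
  imp <- sort(setdiff(in_wgs, discordant))
  s16only <- sort(setdiff(in_s16, c(in_both, in_wgs)))
  pool <- function(tabs, platform) {
    species <- sort(unique(unlist(lapply(tabs, rownames))))
    samples <- unlist(lapply(tabs, colnames))
    out <- matrix(0, length(species), length(samples),
                  dimnames = list(species, samples))
    for (t in tabs) out[rownames(t), colnames(t)] <- abundanceValues(t)
    AbundanceTable(out, platform = platform, unit = "log_cpm")
  }
  s16lc <- pool(lapply(norm, `[[`, "s16"), "S16")
  wgslc <- pool(lapply(norm, `[[`, "wgs"), "WGS")
  meta <- do.call(rbind, lapply(norm, `[[`, "meta"))
  sample_ids <- sampleIds(s16lc)
  meta <- meta[sample_ids, ]
  wgsv <- abundanceValues(wgslc)
  pca <- fitPCs(s16lc, k = pcaK)
  updateFit <- .emptyFit(); imputeFit <- .emptyFit()
  upd_all <- sort(c(upd, discordant))
  imp_all <- sort(c(imp, discordant))
  if (length(upd_all)) {
    s16m <- .s16ValueMatrix(s16lc, upd_all, sample_ids)
    updateFit <- .fitModule(wgsv[upd_all, , drop = FALSE], list(s16 = s16m),
                            .moduleSampleCovariates(NULL, meta, flags, usePCs = FALSE),
                            flags, covMode, K)
  } else warning("no both-platform species in any cohort; update module skipped")
  if (length(imp_all)) {
    pcs <- pca@scores[sample_ids, , drop = FALSE]
    imputeFit <- .fitModule(wgsv[imp_all, , drop = FALSE], list(),
                            .moduleSampleCovariates(pcs, meta, flags, usePCs = TRUE),
                            flags, covMode, K)
  } else warning("no WGS-only species in any cohort; imputation module skipped")
  new("TrainedPredictor",
      updateFit = updateFit, imputeFit = imputeFit, pca = pca,
      partition = new("SpeciesPartition", both = upd, wgsOnly = imp,
                      s16Only = s16only),
      discordant = discordant, variant = variant,
      config = list(pcaK = pcaK, minPrevalence = minPrevalence,
                    covMode = covMode, scale = 1e6, pseudocount = 1,
                    flags = flags, trainedSamples = sample_ids))
}
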