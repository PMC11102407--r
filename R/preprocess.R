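#' @rdname toRelative
#' @aliases toRelative,AbundanceTable-method
#' @details Each sample column is divided by its total. Columns with zero
#'   total cannot be normalized and raise an error naming the offending
#'   samples.
#' @examples
#' m <- matrix(c(2, 3, 5), ncol = 1, dimnames = list(paste("G sp", 1:3), "A"))
#' abundanceValues(toRelative(AbundanceTable(m, "S16", "absolute_count")))
#' @export
setMethod("toRelative", "AbundanceTable", function(x) {
  if (x@unit != "absolute_count")
    stop("toRelative expects absolute_count unit, got ", x@unit)
  v <- abundanceValues(x)
  cs <- colSums(v)
  if (any(cs == 0))
    stop("ZeroLibrary: sample column(s) with zero total: ",
         paste(colnames(v)[cs == 0], collapse = ", "))
  AbundanceTable(sweep(v, 2, cs, "/"), platform = x@platform,
                 unit = "relative_fraction")
})

#' @rdname logCPM
#' @aliases logCPM,AbundanceTable-method
#' @details Applies `x -> log10(scale * x + pseudocount)` per cell. With the
#'   defaults (scale 1e6, pseudocount 1) a zero fraction maps to 0 and the
#'   output is finite and non-negative; the pseudocount is added after
#'   scaling.
#' @export
setMethod("logCPM", "AbundanceTable", function(x, scale = 1e6, pseudocount = 1) {
  if (x@unit != "relative_fraction")
    stop("logCPM expects relative_fraction unit, got ", x@unit)
  v <- abundanceValues(x)
  if (length(v) && any(v < 0)) stop("validation error: negative fractions")
  AbundanceTable(log10(scale * v + pseudocount), platform = x@platform,
                 unit = "log_cpm")
})

#' Normalize a table to the log_cpm working scale
#'
#' Convenience chain: absolute counts are converted to relative fractions and
#' then log-cpm transformed; relative fractions are log-cpm transformed;
#' log_cpm input is returned unchanged.
#'
#' @param x an [AbundanceTable-class] in any unit.
#' @inheritParams logCPM
#' @return An [AbundanceTable-class] in `log_cpm` unit.
#' @export
normalizeToLogCPM <- function(x, scale = 1e6, pseudocount = 1) {
  if (x@unit == "absolute_count") x <- toRelative(x)
  if (x@unit == "relative_fraction") x <- logCPM(x, scale, pseudocount)
  x
}

#' Partition species by detection platform
#'
#' A species is "detected" on a platform iff its abundance is strictly
#' positive in at least `minPrevalence` samples of that platform's table.
#' Every species in the union of the two tables is assigned to exactly one of
#' three sets: detected on both platforms, WGS only, or 16S only.
#'
#' @param s16 16S [AbundanceTable-class] (any unit).
#' @param wgs WGS [AbundanceTable-class] (any unit).
#' @param minPrevalence minimum number of samples with positive abundance
#'   (default 1).
#' @return A [SpeciesPartition-class].
#' @export
partitionSpecies <- function(s16, wgs, minPrevalence = 1) {
  detected <- function(t) {
    v <- abundanceValues(t)
    rownames(v)[rowSums(v > 0) >= minPrevalence]
  }
  d16 <- detected(s16)
  dwgs <- detected(wgs)
  universe <- union(speciesIds(s16), speciesIds(wgs))
  if (!length(universe)) stop("empty species union")
  new("SpeciesPartition",
      both = sort(intersect(d16, dwgs)),
      wgsOnly = sort(setdiff(dwgs, d16)),
      s16Only = sort(setdiff(d16, dwgs)))
}

#' Fit principal-component features of a 16S profile
#'
#' Computes the top `k` principal components of the samples-by-species
#' log_cpm matrix after per-species mean centering (no unit-variance
#' scaling). These sample-level scores summarize the overall 16S profile and
#' serve as the imputation module's fixed-effect covariates. If fewer than `k`
#' non-degenerate components exist, the remaining columns of scores and
#' loadings are zero-padded. Loading signs are fixed deterministically (each
#' column's largest-magnitude entry is made positive).
#'
#' @param s16LogCpm a 16S [AbundanceTable-class] in `log_cpm` unit.
#' @param k number of components to retain (default 10).
#' @return A [PCFeatures-class].
#' @export
fitPCs <- function(s16LogCpm, k = 10) {
  stopifnot(is(s16LogCpm, "AbundanceTable"))
  if (k < 1) stop("k must be >= 1")
  if (s16LogCpm@unit != "log_cpm") stop("fitPCs expects log_cpm unit")
  M <- t(abundanceValues(s16LogCpm))          # samples x species
  if (nrow(M) < 2) stop("at least 2 samples are required")
  center <- colMeans(M)
  Mc <- sweep(M, 2, center, "-")
  sv <- svd(Mc)
  tol <- max(dim(Mc)) * max(sv$d, 0) * .Machine$double.eps
  r <- sum(sv$d > max(tol, 1e-12))
  keff <- min(k, r, ncol(Mc))
  loadings <- matrix(0, ncol(Mc), k, dimnames = list(colnames(M), paste0("PC", seq_len(k))))
  scores <- matrix(0, nrow(M), k, dimnames = list(rownames(M), paste0("PC", seq_len(k))))
  varexp <- numeric(k)
  if (keff > 0) {
    V <- sv$v[, seq_len(keff), drop = FALSE]
    flip <- vapply(seq_len(keff), function(j) {
      jmax <- which.max(abs(V[, j]))
      if (V[jmax, j] < 0) -1 else 1
    }, numeric(1))
    V <- sweep(V, 2, flip, "*")
    loadings[, seq_len(keff)] <- V
    scores[, seq_len(keff)] <- Mc %*% V
    varexp[seq_len(keff)] <- (sv$d[seq_len(keff)]^2) / (nrow(M) - 1)
  }
  new("PCFeatures", scores = scores, loadings = loadings,
      center = center, varExplained = varexp)
}

#' Project new samples onto fitted PC loadings
#'
#' Computes `(new - center) %*% loadings` for a held-out 16S log_cpm table
#' using the training-set loadings. Loading species missing from the new table
#' are treated as 0 (a zero count has log_cpm 0) before centering.
#'
#' @param pca a [PCFeatures-class] from [fitPCs()].
#' @param s16LogCpm a 16S [AbundanceTable-class] in `log_cpm` unit.
#' @return samples-by-k score matrix.
#' @export
projectPCs <- function(pca, s16LogCpm) {
  stopifnot(is(pca, "PCFeatures"), is(s16LogCpm, "AbundanceTable"))
  if (s16LogCpm@unit != "log_cpm") stop("projectPCs expects log_cpm unit")
  species <- rownames(pca@loadings)
  v <- abundanceValues(s16LogCpm)
  M <- matrix(0, ncol(v), length(species),
              dimnames = list(colnames(v), species))
  shared <- intersect(species, rownames(v))
  M[, shared] <- t(v[shared, , drop = FALSE])
  sweep(M, 2, pca@center, "-") %*% pca@loadings
}
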