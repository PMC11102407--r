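# Small programmatic fixtures shared across test files.

tiny_table <- function(values, platform = "S16", unit = "absolute_count") {
  AbundanceTable(values, platform = platform, unit = unit)
}

tiny_paired_cohort <- function(seed = 11, n = 24, mBoth = 6, mWgsOnly = 8,
                               mS16Only = 3, ...) {
  simulateCohort(generatorConfig(nSamples = n, mBoth = mBoth,
                                 mWgsOnly = mWgsOnly, mS16Only = mS16Only,
                                 seed = seed, ...))
}

# The zero-noise, zero-bias limiting scenario: unit platform slope, no species
# offsets, no residual/16S noise, no latent signal into the WGS-only block,
# no metadata effects, no block-mass calibration. Only 16S count rounding
# separates the two platforms.
identity_config <- function(n = 60, seed = 7) {
  generatorConfig(nSamples = n, mBoth = 20, mWgsOnly = 15, mS16Only = 10,
                  beta16s = 1, noiseSd = 0, speciesOffsetSd = 0,
                  s16NoiseSd = 0, baseAbundanceSd = 0.5, factorLoadingSd = 0.3,
                  pcSignalSd = 0,
                  metadataEffect = c(group = 0, timepoint = 0),
                  bothMassTarget = NA, seed = seed)
}

subset_samples <- function(t, ids) {
  AbundanceTable(abundanceValues(t)[, ids, drop = FALSE],
                 platform = platformType(t), unit = abundanceUnit(t))
}

write_tsv_lines <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}

empty_fit <- function() {
  new("FittedLMM", beta = numeric(0), uHat = numeric(0), sigma2e = NA_real_,
      sigma2u = NA_real_, theta = NA_real_, remlLogLik = NA_real_,
      converged = FALSE, covMode = "none", K = matrix(0, 0, 0),
      vcovBeta = matrix(0, 0, 0))
}

max_rel_diff <- function(a, b) {
  if (!length(a) && !length(b)) return(0)
  max(abs(a - b) / pmax(1, abs(b)))
}
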