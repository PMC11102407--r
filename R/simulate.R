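#' Configuration for the paired-cohort simulator
#'
#' Collects the generative parameters of a paired 16S/WGS cohort with the
#' statistical structure the mixed model assumes. The defaults define the
#' package's standard benchmark scenario: 200 samples, 30 species detected on
#' both platforms, 40 WGS-only, 10 16S-only, a platform slope of 0.8 linking
#' 16S to WGS log_cpm, species-offset spread 1.0 and residual noise 0.5 (both
#' in log_cpm units).
#'
#' @param nSamples number of paired samples.
#' @param mBoth,mWgsOnly,mS16Only configured partition sizes.
#' @param beta16s slope linking 16S log_cpm to WGS log_cpm on shared species.
#' @param speciesOffsetSd sd of the per-species random offsets (sigma_u).
#' @param speciesCorr optional correlation matrix (mBoth x mBoth) for the
#'   offsets of shared species (kernel scenario); identity when NULL.
#' @param noiseSd residual noise sd (sigma) on the WGS log_cpm scale.
#' @param nFactors number of latent per-sample factors.
#' @param factorLoadingSd sd of the loadings linking latent factors to 16S
#'   species (log10 scale).
#' @param pcSignal optional mWgsOnly-by-nFactors loading matrix linking latent
#'   factors to WGS-only species; drawn N(0, pcSignalSd^2) when NULL.
#' @param pcSignalSd sd of the drawn pcSignal loadings; set to 0 to remove all
#'   information from the imputation target.
#' @param metadataEffect named vector `c(group = , timepoint = )` of covariate
#'   effects on the WGS log_cpm scale.
#' @param baseAbundanceSd sd of the per-species baseline log10 abundances.
#' @param s16NoiseSd per-cell noise sd of the 16S log-intensities.
#' @param s16OnlyMass fixed total relative-abundance mass of the 16S-only
#'   block in every 16S sample (the shared block carries the rest). Fixing
#'   the block masses keeps the platform-exclusive mass stable across
#'   samples, so compositional closure does not leak sample-specific shifts
#'   into the shared species.
#' @param bothMassTarget mean total relative-abundance mass of the
#'   both-platform block in the WGS table (calibrated by one cohort-wide
#'   constant absorbed by the model intercept); `NA` skips the calibration so
#'   zero-bias scenarios reproduce the 16S fractions exactly.
#' @param wgsOnlyMean mean log_cpm level of WGS-only species.
#' @param librarySize 16S library size; counts are fractions times this,
#'   rounded (rounding noise is part of the emitted data).
#' @param nTimepoints time points are drawn uniformly from 0..(nTimepoints-1).
#' @param seed integer seed; the same seed reproduces the cohort exactly.
#' @return A `GeneratorConfig` (named list).
#' @export
generatorConfig <- function(nSamples = 200, mBoth = 30, mWgsOnly = 40,
                            mS16Only = 10, beta16s = 0.8, speciesOffsetSd = 1.0,
                            speciesCorr = NULL, noiseSd = 0.5, nFactors = 5,
                            factorLoadingSd = 0.5, pcSignal = NULL,
                            pcSignalSd = 0.5,
                            metadataEffect = c(group = 0.3, timepoint = 0.1),
                            baseAbundanceSd = 0.8, s16NoiseSd = 0.3,
                            s16OnlyMass = 0.15,
                            bothMassTarget = 0.3, wgsOnlyMean = NA,
                            librarySize = 50000, nTimepoints = 3, seed = 1) {
  cfg <- as.list(environment())
  stopifnot(cfg$nSamples >= 2, cfg$mBoth >= 0, cfg$mWgsOnly >= 0, cfg$mS16Only >= 0,
            cfg$noiseSd >= 0, cfg$speciesOffsetSd >= 0, cfg$s16NoiseSd >= 0)
  if (cfg$mBoth + cfg$mWgsOnly + cfg$mS16Only < 1)
    stop("infeasible partition sizes: empty species universe")
  if (!is.null(cfg$speciesCorr)) {
    sc <- as.matrix(cfg$speciesCorr)
    if (!all(dim(sc) == c(cfg$mBoth, cfg$mBoth)))
      stop("speciesCorr must be mBoth x mBoth")
    ev <- eigen(sc, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) stop("speciesCorr must be positive semidefinite")
  }
  class(cfg) <- c("GeneratorConfig", "list")
  cfg
}

# Draw MVN(0, sd^2 * C) offsets; C = I when NULL.
.drawOffsets <- function(m, sd, C = NULL) {
  z <- rnorm(m)
  if (is.null(C) || sd == 0) return(sd * z)
  ev <- eigen(as.matrix(C), symmetric = TRUE)
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), m)
  sd * drop(L %*% z)
}

#' Simulate a paired 16S/WGS cohort
#'
#' Generates a cohort realizing the configured partition sizes exactly.
#' Per-sample latent factors drive the 16S composition (so its principal
#' components carry signal); the WGS log_cpm of each shared species is
#' `slope * (16S log_cpm) + species offset + metadata effects + noise`, and
#' WGS-only species are driven by the latent factors through the `pcSignal`
#' loadings. The structural relation is inverted exactly into the emitted
#' tables: shared-species WGS fractions are `(10^w - 1) / 1e6` (one
#' cohort-wide scale constant calibrates the block mass and is absorbed by
#' the model intercept), and WGS-only species fill the remaining column mass.
#' The 16S table is emitted as absolute counts (fractions times the library
#' size, rounded), so the full normalization chain is exercised downstream.
#'
#' @param cfg a [generatorConfig()].
#' @return list: `s16` (counts [AbundanceTable-class]), `wgs`
#'   (relative-fraction [AbundanceTable-class]), `meta` (data.frame), `truth`
#'   (generating parameters and latent values).
#' @export
simulateCohort <- function(cfg = generatorConfig()) {
  stopifnot(inherits(cfg, "GeneratorConfig"))
  withLocalSeed(cfg$seed, .simulateCohortImpl(cfg))
}

.simulateCohortImpl <- function(cfg, speciesNames = NULL) {
  n <- cfg$nSamples
  sp_both <- sprintf("Synthbacter both%03d", seq_len(cfg$mBoth))
  sp_wgs <- sprintf("Synthbacter wgs%03d", seq_len(cfg$mWgsOnly))
  sp_s16 <- sprintf("Synthbacter amp%03d", seq_len(cfg$mS16Only))
  if (!is.null(speciesNames)) {
    sp_both <- speciesNames$both; sp_wgs <- speciesNames$wgsOnly
    sp_s16 <- speciesNames$s16Only
  }
  samples <- sprintf("S%04d", seq_len(n))
  meta <- data.frame(sample_id = samples,
                     group = rbinom(n, 1, 0.5),
                     timepoint = sample.int(cfg$nTimepoints, n, replace = TRUE) - 1L,
                     stringsAsFactors = FALSE)

  # --- 16S side: latent-factor-driven composition, emitted as counts -----
  s16_species <- c(sp_both, sp_s16)
  m16 <- length(s16_species)
  f <- matrix(rnorm(n * cfg$nFactors), n, cfg$nFactors)      # latent factors
  base16 <- rnorm(m16, 0, cfg$baseAbundanceSd)
  Lam <- matrix(rnorm(m16 * cfg$nFactors, 0, cfg$factorLoadingSd), m16, cfg$nFactors)
  logint <- base16 + Lam %*% t(f) +
    matrix(rnorm(m16 * n, 0, cfg$s16NoiseSd), m16, n)        # species x sample
  intens <- 10^logint
  # block-structured composition: the shared and 16S-only blocks carry fixed
  # total masses, the within-block proportions follow the latent intensities
  mass16only <- if (cfg$mS16Only == 0) 0 else if (cfg$mBoth == 0) 1 else cfg$s16OnlyMass
  frac16 <- matrix(0, m16, n)
  if (cfg$mBoth > 0) {
    blk <- intens[seq_len(cfg$mBoth), , drop = FALSE]
    frac16[seq_len(cfg$mBoth), ] <- sweep(blk, 2, colSums(blk), "/") * (1 - mass16only)
  }
  if (cfg$mS16Only > 0) {
    idx <- cfg$mBoth + seq_len(cfg$mS16Only)
    blk <- intens[idx, , drop = FALSE]
    frac16[idx, ] <- sweep(blk, 2, colSums(blk), "/") * mass16only
  }
  dimnames(frac16) <- list(s16_species, samples)
  counts16 <- round(frac16 * cfg$librarySize)
  # realize the configured partition exactly: every 16S species must be
  # detected in at least one sample after rounding
  zero_rows <- which(rowSums(counts16) == 0)
  for (i in zero_rows) counts16[i, which.max(frac16[i, ])] <- 1
  v16 <- log10(1e6 * frac16 + 1)                             # pre-rounding log_cpm

  # --- WGS side: structural model on the log_cpm scale -------------------
  u <- .drawOffsets(cfg$mBoth, cfg$speciesOffsetSd, cfg$speciesCorr)
  eff <- cfg$metadataEffect
  if (is.null(names(eff))) names(eff) <- c("group", "timepoint")
  meta_term <- outer(rep(1, cfg$mBoth),
                     eff[["group"]] * meta$group + eff[["timepoint"]] * meta$timepoint)
  w_both <- cfg$beta16s * v16[sp_both, , drop = FALSE] + u + meta_term +
    matrix(rnorm(cfg$mBoth * n, 0, cfg$noiseSd), cfg$mBoth, n)
  # one cohort-wide scale constant calibrates the both-block mass; it shifts
  # every w by the same amount and is absorbed by the model intercept
  intercept_shift <- 0
  x_both <- matrix(0, 0, n)
  if (cfg$mBoth > 0) {
    raw_mass <- colSums(pmax(10^w_both - 1, 0)) / 1e6
    # NA target skips the calibration (used by exact-identity scenarios)
    cscale <- if (is.na(cfg$bothMassTarget)) 1 else cfg$bothMassTarget / mean(raw_mass)
    intercept_shift <- log10(cscale)
    w_both <- w_both + intercept_shift
    x_both <- pmax((10^w_both - 1) / 1e6, 1e-8)
    # safety: a column's both-block may not (almost) exhaust the simplex
    over <- colSums(x_both) > 0.95
    if (any(over)) x_both[, over] <- sweep(x_both[, over, drop = FALSE], 2,
                                           colSums(x_both[, over, drop = FALSE]) / 0.95, "/")
  }
  wgs_only_mean <- if (is.na(cfg$wgsOnlyMean)) {
    # aim the WGS-only block at the leftover mass spread over its species
    leftover <- max(1 - mean(colSums(x_both)), 0.05)
    log10(1e6 * leftover / max(cfg$mWgsOnly, 1)) - 0.5
  } else cfg$wgsOnlyMean
  x_wgs_only <- matrix(0, 0, n)
  P <- matrix(0, cfg$mWgsOnly, cfg$nFactors)
  if (cfg$mWgsOnly > 0) {
    P <- if (is.null(cfg$pcSignal))
      matrix(rnorm(cfg$mWgsOnly * cfg$nFactors, 0, cfg$pcSignalSd),
             cfg$mWgsOnly, cfg$nFactors)
    else as.matrix(cfg$pcSignal)
    base_wgs <- rnorm(cfg$mWgsOnly, wgs_only_mean, cfg$baseAbundanceSd)
    w_only <- base_wgs + P %*% t(f) +
      outer(rep(1, cfg$mWgsOnly),
            eff[["group"]] * meta$group + eff[["timepoint"]] * meta$timepoint) +
      matrix(rnorm(cfg$mWgsOnly * n, 0, cfg$noiseSd), cfg$mWgsOnly, n)
    x_only_raw <- pmax((10^w_only - 1) / 1e6, 1e-8)
    leftover <- pmax(1 - if (cfg$mBoth > 0) colSums(x_both) else 0, 0.02)
    x_wgs_only <- sweep(x_only_raw, 2, leftover / colSums(x_only_raw), "*")
  } else if (cfg$mBoth > 0) {
    # no WGS-only species: the both block must itself be compositional
    x_both <- sweep(x_both, 2, colSums(x_both), "/")
  }
  x_wgs <- rbind(x_both, x_wgs_only)
  dimnames(x_wgs) <- list(c(sp_both, sp_wgs), samples)
  # partitions are detection-based: keep every WGS species strictly positive
  x_wgs[x_wgs <= 0] <- 1e-8
  x_wgs <- sweep(x_wgs, 2, colSums(x_wgs), "/")

  s16 <- AbundanceTable(counts16, platform = "S16", unit = "absolute_count")
  wgs <- AbundanceTable(x_wgs, platform = "WGS", unit = "relative_fraction")
  if (cfg$mBoth > 0) dimnames(w_both) <- list(sp_both, samples)
  list(s16 = s16, wgs = wgs, meta = meta,
       truth = list(config = cfg, u = setNames(u, sp_both), factors = f,
                    loadings16 = Lam, pcSignal = P,
                    interceptShift = intercept_shift,
                    bothSpecies = sp_both, wgsOnlySpecies = sp_wgs,
                    s16OnlySpecies = sp_s16,
                    v16PreRounding = v16,
                    wBothStructural = w_both))
}

#' Simulate a multi-cohort collection with discordant species
#'
#' Generates cohorts over a shared species universe. In every cohort after
#' the first, a configured fraction of the shared ("both-platform") species
#' is instead detected by WGS only — the discordant species that a
#' multi-cohort model fits in both modules and scores by averaging.
#'
#' @param cfgs list of [generatorConfig()]s (>= 2) sharing `mBoth`,
#'   `mWgsOnly`, `mS16Only`.
#' @param discordantFraction fraction of the shared species made WGS-only in
#'   cohorts 2..k (in \[0, 1\]).
#' @return list of cohorts (as from [simulateCohort()]); sample ids carry a
#'   cohort prefix.
#' @export
simulateMulticohort <- function(cfgs, discordantFraction = 0.2) {
  stopifnot(length(cfgs) >= 2)
  if (discordantFraction < 0 || discordantFraction > 1)
    stop("discordantFraction must be in [0, 1]")
  sizes <- vapply(cfgs, function(c) c(c$mBoth, c$mWgsOnly, c$mS16Only), numeric(3))
  if (any(apply(sizes, 1, function(x) length(unique(x)) != 1)))
    stop("all configs must share the same species universe sizes")
  m_disc <- floor(discordantFraction * cfgs[[1]]$mBoth)
  base_names <- list(
    both = sprintf("Synthbacter both%03d", seq_len(cfgs[[1]]$mBoth)),
    wgsOnly = sprintf("Synthbacter wgs%03d", seq_len(cfgs[[1]]$mWgsOnly)),
    s16Only = sprintf("Synthbacter amp%03d", seq_len(cfgs[[1]]$mS16Only)))
  lapply(seq_along(cfgs), function(i) {
    cfg <- cfgs[[i]]
    nm <- base_names
    if (i > 1 && m_disc > 0) {
      # the last m_disc shared species become WGS-only in this cohort
      disc <- nm$both[seq(length(nm$both) - m_disc + 1L, length(nm$both))]
      nm$both <- setdiff(nm$both, disc)
      nm$wgsOnly <- c(nm$wgsOnly, disc)
      cfg$mBoth <- cfg$mBoth - m_disc
      cfg$mWgsOnly <- cfg$mWgsOnly + m_disc
    }
    co <- withLocalSeed(cfg$seed, .simulateCohortImpl(cfg, speciesNames = nm))
    rename <- function(t) {
      v <- abundanceValues(t)
      colnames(v) <- paste0("C", i, "_", colnames(v))
      AbundanceTable(v, platform = platformType(t), unit = abundanceUnit(t))
    }
    co$s16 <- rename(co$s16); co$wgs <- rename(co$wgs)
    co$meta$sample_id <- paste0("C", i, "_", co$meta$sample_id)
    co
  })
}
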