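test_that("identity cohort recovers a unit 16S slope with tiny BLUPs", {
  co <- simulateCohort(identity_config(n = 40, seed = 7))
  tp <- trainPredictor(co$s16, co$wgs, co$meta, pcaK = 6)
  expect_equal(unname(tp@updateFit@beta[["s16"]]), 1, tolerance = 0.02)
  expect_lt(max(abs(blup(tp@updateFit))), 0.05)
})

test_that("scoring covers both modules with the right shapes and tags", {
  co <- tiny_paired_cohort(seed = 21)
  tp <- trainPredictor(co$s16, co$wgs, co$meta, pcaK = 5)
  pr <- predict(tp, co$s16, co$meta)
  part <- tp@partition
  expect_equal(nrow(predictedTable(pr)),
               length(bothSpecies(part)) + length(wgsOnlySpecies(part)))
  expect_setequal(unique(provenance(pr)), c("updated", "imputed"))
  expect_equal(unname(provenance(pr)[bothSpecies(part)]),
               rep("updated", length(bothSpecies(part))))
  # 16S-only species are excluded by default, appended on request
  pr2 <- predict(tp, co$s16, co$meta, passthroughS16Only = TRUE)
  expect_equal(nrow(predictedTable(pr2)),
               nrow(predictedTable(pr)) + length(s16OnlySpecies(part)))
  expect_equal(unname(provenance(pr2)[s16OnlySpecies(part)]),
               rep("passthrough", length(s16OnlySpecies(part))))
})

test_that("scoring a training sample reproduces the modules' fitted values", {
  co <- tiny_paired_cohort(seed = 2)
  tp <- trainPredictor(co$s16, co$wgs, co$meta, pcaK = 4)
  pr <- predict(tp, co$s16, co$meta)
  # recompute update-module fitted values by hand for one species/sample
  s16lc <- normalizeToLogCPM(co$s16)
  sp <- bothSpecies(tp@partition)[1]
  smp <- sampleIds(co$s16)[3]
  x16 <- abundanceValues(s16lc)[sp, smp]
  md <- co$meta[co$meta$sample_id == smp, ]
  b <- tp@updateFit@beta
  manual <- b[["(Intercept)"]] + b[["s16"]] * x16 + b[["group"]] * md$group +
    b[["timepoint"]] * md$timepoint + blup(tp@updateFit)[[sp]]
  expect_equal(abundanceValues(predictedTable(pr))[sp, smp], manual,
               tolerance = 1e-10)
})

test_that("an all-zero 16S sample still yields finite predictions", {
  co <- tiny_paired_cohort(seed = 23)
  tp <- trainPredictor(co$s16, co$wgs, co$meta, pcaK = 4)
  zero <- AbundanceTable(matrix(0, nrow(co$s16), 1,
    dimnames = list(speciesIds(co$s16), "Z1")), "S16", "log_cpm")
  meta0 <- data.frame(sample_id = "Z1", group = 0, timepoint = 0)
  pr <- predict(tp, zero, meta0)
  expect_true(all(is.finite(abundanceValues(predictedTable(pr)))))
})

test_that("update predictions are monotone in the 16S value when the slope is positive", {
  co <- tiny_paired_cohort(seed = 31)
  tp <- trainPredictor(co$s16, co$wgs, co$meta, pcaK = 4)
  expect_gt(tp@updateFit@beta[["s16"]], 0)
  sp <- bothSpecies(tp@partition)[1]
  X <- cbind(`(Intercept)` = 1, s16 = c(1, 2, 3), group = 0, timepoint = 0)
  pr <- predict(tp@updateFit, X, rep(sp, 3))
  expect_true(all(diff(pr) > 0))
})

test_that("degenerate cohorts drop the empty module with a warning", {
  co <- tiny_paired_cohort(seed = 41, mWgsOnly = 0)
  expect_warning(tp <- trainPredictor(co$s16, co$wgs, co$meta, pcaK = 3),
                 "imputation module skipped")
  expect_length(tp@imputeFit@uHat, 0)
  pr <- predict(tp, co$s16, co$meta)
  expect_setequal(unique(provenance(pr)), "updated")
})

test_that("unpaired samples and missing metadata are refused by name", {
  co <- tiny_paired_cohort(seed = 43, n = 10)
  s16_drop <- subset_samples(co$s16, sampleIds(co$s16)[-1])
  expect_error(trainPredictor(s16_drop, co$wgs, co$meta), "unpaired.*S0001")
  tp <- trainPredictor(co$s16, co$wgs, co$meta, pcaK = 3)
  expect_error(predict(tp, co$s16, co$meta[-2, ]), "metadata missing.*S0002")
})

test_that("training and scoring are deterministic end to end", {
  co <- tiny_paired_cohort(seed = 3)
  run <- function() {
    tp <- trainPredictor(co$s16, co$wgs, co$meta, pcaK = 5)
    abundanceValues(predictedTable(predict(tp, co$s16, co$meta)))
  }
  expect_identical(run(), run())
})

test_that("model bundles round-trip through JSON with identical predictions", {
  co <- tiny_paired_cohort(seed = 19, n = 12)
  tp <- trainPredictor(co$s16, co$wgs, co$meta, pcaK = 3)
  path <- tempfile(fileext = ".json")
  saveModelBundle(tp, path)
  tp2 <- readModelBundle(path)
  p1 <- abundanceValues(predictedTable(predict(tp, co$s16, co$meta)))
  p2 <- abundanceValues(predictedTable(predict(tp2, co$s16, co$meta)))
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("multi-cohort training averages discordant species", {
  cfgs <- list(generatorConfig(nSamples = 16, mBoth = 8, mWgsOnly = 6,
                               mS16Only = 3, seed = 51),
               generatorConfig(nSamples = 16, mBoth = 8, mWgsOnly = 6,
                               mS16Only = 3, seed = 52))
  cohorts <- simulateMulticohort(cfgs, discordantFraction = 0.25)
  tp <- trainMulticohort(cohorts, pcaK = 4)
  expect_length(tp@discordant, 2)  # floor(0.25 * 8)
  new16 <- cohorts[[1]]$s16
  pr <- predict(tp, new16, cohorts[[1]]$meta)
  expect_equal(unname(provenance(pr)[tp@discordant]), rep("averaged", 2))
  # the averaged value equals the arithmetic mean of the two module predictions
  s16lc <- normalizeToLogCPM(new16)
  smp <- sampleIds(new16)[1]
  md <- cohorts[[1]]$meta[cohorts[[1]]$meta$sample_id == smp, ]
  sp <- tp@discordant[1]
  bu <- tp@updateFit@beta
  upd <- bu[["(Intercept)"]] + bu[["s16"]] * abundanceValues(s16lc)[sp, smp] +
    bu[["group"]] * md$group + bu[["timepoint"]] * md$timepoint +
    blup(tp@updateFit)[[sp]]
  pcs <- projectPCs(tp@pca, s16lc)[smp, ]
  bi <- tp@imputeFit@beta
  imp <- bi[["(Intercept)"]] + sum(bi[paste0("PC", 1:4)] * pcs) +
    bi[["group"]] * md$group + bi[["timepoint"]] * md$timepoint +
    blup(tp@imputeFit)[[sp]]
  expect_equal(abundanceValues(predictedTable(pr))[sp, smp], (upd + imp) / 2,
               tolerance = 1e-10)
  # union bookkeeping: output covers update + impute + discordant exactly once
  expect_equal(nrow(predictedTable(pr)),
               length(bothSpecies(tp@partition)) +
                 length(wgsOnlySpecies(tp@partition)) + length(tp@discordant))
})

test_that("a single-cohort multi-cohort call reduces to plain training", {
  co <- tiny_paired_cohort(seed = 61, n = 12)
  tp1 <- trainPredictor(co$s16, co$wgs, co$meta, pcaK = 3)
  tp2 <- trainMulticohort(list(list(s16 = co$s16, wgs = co$wgs, meta = co$meta)),
                          pcaK = 3)
  expect_equal(tp1@updateFit@beta, tp2@updateFit@beta)
  expect_equal(blup(tp1@imputeFit), blup(tp2@imputeFit))
  # overlapping sample ids across cohorts are refused
  expect_error(trainMulticohort(list(
    list(s16 = co$s16, wgs = co$wgs, meta = co$meta),
    list(s16 = co$s16, wgs = co$wgs, meta = co$meta))), "overlapping")
})
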