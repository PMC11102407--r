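test_that("toRelative divides by column totals and flags empty libraries", {
  m <- matrix(c(2, 3, 5, 0, 0, 10), 3, 2,
              dimnames = list(paste("G sp", 1:3), c("A", "B")))
  rel <- toRelative(tiny_table(m))
  expect_equal(unname(abundanceValues(rel)[, "A"]), c(0.2, 0.3, 0.5))
  expect_equal(unname(abundanceValues(rel)[, "B"]), c(0, 0, 1))
  expect_equal(unname(colSums(abundanceValues(rel))), c(1, 1))
  m0 <- m; m0[, "B"] <- 0
  expect_error(toRelative(tiny_table(m0)), "ZeroLibrary.*B")
})

test_that("log_cpm transform matches direct arithmetic and is monotone", {
  m <- cbind(A = c(0, 1e-6, 1 - 1e-6), B = c(0, 1, 0))
  rownames(m) <- paste("G sp", 1:3)
  lc <- logCPM(tiny_table(m, unit = "relative_fraction"))
  v <- abundanceValues(lc)
  expect_equal(v["G sp 1", "A"], 0)                       # log10(1) = 0
  expect_equal(v["G sp 2", "A"], log10(2), tolerance = 1e-12)
  expect_equal(v["G sp 2", "B"], log10(1000001), tolerance = 1e-12)
  # strictly monotone in the fraction
  x <- sort(runif(50))
  expect_true(all(diff(log10(1e6 * x + 1)) > 0))
})

test_that("species partition is disjoint and exhaustive", {
  s16 <- tiny_table(matrix(c(1, 1, 1, 0), 4, 1,
    dimnames = list(c("A sp", "B sp", "C sp", "D sp"), "S1")))
  wgs <- tiny_table(matrix(c(0, 1, 1, 1), 4, 1,
    dimnames = list(c("A sp", "B sp", "C sp", "D sp"), "S1")), platform = "WGS")
  p <- partitionSpecies(s16, wgs)
  expect_equal(bothSpecies(p), c("B sp", "C sp"))
  expect_equal(wgsOnlySpecies(p), "D sp")
  expect_equal(s16OnlySpecies(p), "A sp")

  # identity: identical tables leave nothing platform-exclusive
  pid <- partitionSpecies(s16, tiny_table(abundanceValues(s16), platform = "WGS"))
  expect_length(wgsOnlySpecies(pid), 0)
  expect_length(s16OnlySpecies(pid), 0)

  # property: disjoint + exhaustive for random presence patterns
  set.seed(91)
  for (i in 1:20) {
    ns <- sample(3:12, 1)
    sp <- sprintf("Genus sp%02d", seq_len(ns))
    mk <- function() tiny_table(matrix(rbinom(ns * 4, 1, 0.5), ns, 4,
      dimnames = list(sp, paste0("S", 1:4))))
    a <- mk(); b <- mk()
    detected <- union(sp[rowSums(abundanceValues(a) > 0) > 0],
                      sp[rowSums(abundanceValues(b) > 0) > 0])
    if (!length(detected)) next
    p <- partitionSpecies(a, b)
    all_assigned <- c(bothSpecies(p), wgsOnlySpecies(p), s16OnlySpecies(p))
    expect_equal(anyDuplicated(all_assigned), 0L)
    expect_setequal(all_assigned, detected)
  }
})

test_that("minPrevalence controls the detection rule", {
  m <- matrix(c(1, 0, 0, 0, 2, 3), 2, 3, byrow = TRUE,
              dimnames = list(c("A sp", "B sp"), paste0("S", 1:3)))
  s16 <- tiny_table(m)            # A sp in 1 sample, B sp in 2
  wgs_m <- m[2:1, , drop = FALSE] # swap values, keep names: A sp in 2, B sp in 1
  rownames(wgs_m) <- c("A sp", "B sp")
  wgs <- tiny_table(wgs_m, platform = "WGS")
  p1 <- partitionSpecies(s16, wgs, minPrevalence = 1)
  expect_setequal(bothSpecies(p1), c("A sp", "B sp"))
  p2 <- partitionSpecies(s16, wgs, minPrevalence = 2)
  expect_equal(s16OnlySpecies(p2), "B sp")
  expect_equal(wgsOnlySpecies(p2), "A sp")
})

test_that("PC features reconstruct, orthonormalize and zero-pad", {
  set.seed(31)
  # rank-1 input: one profile scaled per sample
  profile <- rnorm(6)
  scalars <- runif(5, 0.5, 2)
  m1 <- outer(profile, scalars)
  dimnames(m1) <- list(sprintf("G sp%d", 1:6), sprintf("S%d", 1:5))
  pca1 <- fitPCs(tiny_table(m1, unit = "log_cpm"), k = 4)
  expect_gt(pca1@varExplained[1], 0)
  expect_equal(pca1@varExplained[-1], rep(0, 3))
  expect_equal(unname(pca1@scores[, 2:4]), matrix(0, 5, 3))

  # 3 samples, k = 10: columns 3..10 of the features are zero-padded
  m2 <- matrix(rnorm(30), 10, 3,
               dimnames = list(sprintf("G sp%d", 1:10), sprintf("S%d", 1:3)))
  pca2 <- fitPCs(tiny_table(m2, unit = "log_cpm"), k = 10)
  expect_equal(ncol(pca2@scores), 10)
  expect_equal(unname(pca2@scores[, 3:10]), matrix(0, 3, 8))

  # reconstruction when k >= rank, orthonormal loadings, ordered variances
  m3 <- matrix(rnorm(8 * 12), 8, 12,
               dimnames = list(sprintf("G sp%d", 1:8), sprintf("S%d", 1:12)))
  pca3 <- fitPCs(tiny_table(m3, unit = "log_cpm"), k = 8)
  L <- pca3@loadings
  expect_equal(crossprod(L), diag(8), tolerance = 1e-8, ignore_attr = TRUE)
  recon <- pca3@scores %*% t(L) + matrix(pca3@center, 12, 8, byrow = TRUE)
  expect_equal(unname(recon), unname(t(m3)), tolerance = 1e-8)
  expect_true(all(diff(pca3@varExplained) <= 1e-10))

  # features equal centered-input %*% loadings
  Mc <- sweep(t(m3), 2, pca3@center, "-")
  expect_equal(pca3@scores, Mc %*% L, tolerance = 1e-8)
})

test_that("PC sign convention is deterministic", {
  set.seed(8)
  m <- matrix(rnorm(40), 5, 8, dimnames = list(sprintf("G sp%d", 1:5),
                                               sprintf("S%d", 1:8)))
  pca <- fitPCs(tiny_table(m, unit = "log_cpm"), k = 3)
  for (j in 1:3) {
    col <- pca@loadings[, j]
    expect_gte(col[which.max(abs(col))], 0)
  }
})

test_that("projection reproduces training scores and centers the mean profile", {
  co <- tiny_paired_cohort(seed = 13)
  s16lc <- normalizeToLogCPM(co$s16)
  pca <- fitPCs(s16lc, k = 5)
  proj <- projectPCs(pca, s16lc)
  expect_equal(proj, pca@scores, tolerance = 1e-8)
  # a sample equal to the training mean profile projects to zero
  mean_tab <- tiny_table(matrix(pca@center, ncol = 1,
    dimnames = list(names(pca@center), "MEAN")), unit = "log_cpm")
  expect_equal(unname(projectPCs(pca, mean_tab)), matrix(0, 1, 5),
               tolerance = 1e-10)
  # single held-out sample gives a 1 x k row
  one <- subset_samples(s16lc, sampleIds(s16lc)[1])
  expect_equal(dim(projectPCs(pca, one)), c(1L, 5L))
})
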