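test_that("buildDesign flattens species-major with a per-species indicator", {
  set.seed(14)
  resp <- matrix(rnorm(9), 3, 3, dimnames = list(sprintf("G sp%d", 1:3),
                                                 c("A", "B", "C")))
  xc <- matrix(rnorm(9), 3, 3, dimnames = dimnames(resp))
  spec <- buildDesign(resp, cellCovariates = list(s16 = xc))
  expect_length(spec@y, 9)
  expect_equal(spec@y[1:3], unname(resp[1, ]))   # species 1 block first
  Z <- designZ(spec)
  expect_equal(dim(Z), c(9L, 3L))
  expect_equal(unname(colSums(Z)), rep(3, 3))
  expect_true(all(rowSums(Z) == 1))
  # update-module design: intercept + 16S value + group + timepoint = 4 cols
  meta <- cbind(group = c(0, 1, 1), timepoint = c(0, 2, 1))
  spec_u <- buildDesign(resp, cellCovariates = list(s16 = xc),
                        sampleCovariates = meta)
  expect_equal(ncol(spec_u@X), 4L)
  # imputation-module design: intercept + 10 PCs + group + timepoint = 13 cols
  resp_w <- matrix(rnorm(45), 3, 15, dimnames = list(rownames(resp),
                                                     sprintf("S%02d", 1:15)))
  pcs <- matrix(rnorm(150), 15, 10,
                dimnames = list(colnames(resp_w), paste0("PC", 1:10)))
  meta_w <- cbind(group = rbinom(15, 1, 0.5), timepoint = sample(0:2, 15, TRUE))
  spec_i <- buildDesign(resp_w, sampleCovariates = cbind(pcs, meta_w))
  expect_equal(ncol(spec_i@X), 13L)
  # misalignment and rank deficiency are errors
  expect_error(buildDesign(resp, cellCovariates = list(bad = xc[, 1, drop = FALSE])),
               "misaligned")
  expect_error(buildDesign(resp, sampleCovariates = cbind(a = c(1, 1, 1))),
               "rank deficient")
})

test_that("profiled REML log-likelihood matches the dense formula", {
  for (seed in c(2, 17, 23)) {
    inst <- random_small_instance(seed)
    spec <- buildDesign(inst$resp, cellCovariates = list(x = inst$xc),
                        sampleCovariates = cbind(g = inst$g))
    d <- dense_design(inst)
    for (theta in c(0, 0.3, 1, 4)) {
      expect_equal(remlLogLik(spec, theta),
                   dense_reml_loglik(theta, d$y, d$X, d$Z)$loglik,
                   tolerance = 1e-8)
    }
  }
})

test_that("kernel-mode REML matches the dense formula with a species kernel", {
  inst <- random_small_instance(41, kernel = TRUE)
  spec <- buildDesign(inst$resp, cellCovariates = list(x = inst$xc),
                      sampleCovariates = cbind(g = inst$g),
                      covMode = "kernel", K = inst$K)
  d <- dense_design(inst)
  for (theta in c(0, 0.5, 2))
    expect_equal(remlLogLik(spec, theta),
                 dense_reml_loglik(theta, d$y, d$X, d$Z, inst$K)$loglik,
                 tolerance = 1e-8)
  fit <- remlFit(spec)
  oracle <- dense_reml_fit(d$y, d$X, d$Z, inst$K)
  expect_lt(max_rel_diff(unname(fit@beta), oracle$beta), 1e-5)
  expect_lt(max_rel_diff(unname(blup(fit)), oracle$uHat), 1e-5)
})

test_that("REML agrees with lme4 on a medium random-intercept instance", {
  set.seed(99)
  n <- 30; m <- 5
  species <- sprintf("sp%d", 1:m); samples <- sprintf("S%02d", 1:n)
  xc <- matrix(rnorm(n * m), m, n, dimnames = list(species, samples))
  u <- rnorm(m, 0, 1.1)
  resp <- 1 + 0.7 * xc + outer(u, rep(1, n)) + matrix(rnorm(m * n, 0, 0.5), m, n)
  dimnames(resp) <- dimnames(xc)
  spec <- buildDesign(resp, cellCovariates = list(x = xc))
  fit <- remlFit(spec)
  df <- data.frame(y = spec@y, x = spec@X[, "x"], sp = spec@species)
  lf <- lme4::lmer(y ~ x + (1 | sp), data = df, REML = TRUE)
  expect_equal(unname(fit@beta), unname(lme4::fixef(lf)), tolerance = 1e-5)
  vc <- as.data.frame(lme4::VarCorr(lf))
  expect_equal(fit@sigma2u, vc$vcov[1], tolerance = 1e-4)
  expect_equal(fit@sigma2e, vc$vcov[2], tolerance = 1e-4)
  expect_equal(fit@remlLogLik, as.numeric(stats::logLik(lf)), tolerance = 1e-6)
  expect_equal(unname(blup(fit)), lme4::ranef(lf)$sp[, 1], tolerance = 1e-5)
})

test_that("boundary and scaling identities hold", {
  # species-centered response forces the theta = 0 boundary without NaN
  set.seed(5)
  inst <- random_small_instance(5)
  resp <- inst$resp - rowMeans(inst$resp)
  spec <- buildDesign(resp, cellCovariates = list(x = inst$xc))
  fit <- remlFit(spec)
  expect_equal(fit@theta, 0)
  expect_equal(fit@sigma2u, 0)
  expect_true(all(is.finite(c(fit@beta, fit@sigma2e, fit@remlLogLik))))
  # at theta = 0 predictions equal OLS
  ols <- fitLR(spec)
  expect_equal(fit@beta, ols@beta, tolerance = 1e-8)
  # doubling y doubles the scale: sigma2 x4, loglik shifts by -(N-p) log 2
  spec2 <- buildDesign(2 * inst$resp, cellCovariates = list(x = inst$xc))
  f1 <- remlFit(buildDesign(inst$resp, cellCovariates = list(x = inst$xc)))
  f2 <- remlFit(spec2)
  expect_equal(f2@sigma2e, 4 * f1@sigma2e, tolerance = 1e-5)
  expect_equal(f2@theta, f1@theta, tolerance = 1e-4)
  Np <- length(spec2@y) - ncol(spec2@X)
  expect_equal(f2@remlLogLik, f1@remlLogLik - Np * log(2), tolerance = 1e-6)
})

test_that("BLUPs shrink species means and are centered under an intercept", {
  set.seed(77)
  n <- 12; m <- 6
  species <- sprintf("sp%d", 1:m); samples <- sprintf("S%02d", 1:n)
  resp <- outer(rnorm(m, 0, 1), rep(1, n)) + matrix(rnorm(m * n, 0, 0.8), m, n)
  dimnames(resp) <- list(species, samples)
  spec <- buildDesign(resp)       # intercept-only fixed effects
  fit <- remlFit(spec)
  # balanced diagonal case: u_j = (n g / (1 + n g)) * mean residual of species j
  g <- fit@theta^2
  resid_means <- rowMeans(resp) - fit@beta[["(Intercept)"]]
  expect_equal(unname(blup(fit)), unname((n * g / (1 + n * g)) * resid_means),
               tolerance = 1e-8)
  # closed-form ANOVA estimators on the balanced design
  mse <- sum((resp - rowMeans(resp))^2) / (m * (n - 1))
  msa <- n * sum((rowMeans(resp) - mean(resp))^2) / (m - 1)
  expect_equal(fit@sigma2e, mse, tolerance = 1e-6)
  expect_equal(fit@sigma2u, (msa - mse) / n, tolerance = 1e-6)
  # BLUPs sum to ~0 when X contains an intercept
  expect_lt(abs(sum(blup(fit))), 1e-6)
})

test_that("fitted-model predictions are consistent and species-aware", {
  inst <- random_small_instance(12)
  spec <- buildDesign(inst$resp, cellCovariates = list(x = inst$xc),
                      sampleCovariates = cbind(g = inst$g))
  fit <- remlFit(spec)
  # a training row predicts its own fitted value
  yhat <- predict(fit, spec@X, spec@species)
  i <- 3L
  expect_equal(predict(fit, spec@X[i, , drop = FALSE],
                       as.character(spec@species[i])),
               unname(yhat[i]))
  # two rows with equal covariates but different species differ by the BLUP gap
  X0 <- spec@X[c(1, 1), , drop = FALSE]
  sps <- levels(spec@species)[1:2]
  pr <- predict(fit, X0, sps)
  expect_equal(unname(diff(pr)), unname(blup(fit)[sps[2]] - blup(fit)[sps[1]]),
               tolerance = 1e-10)
  expect_error(predict(fit, X0, c("nope sp", sps[1])), "not seen in training")
})

test_that("estimates are invariant to sample permutation", {
  inst <- random_small_instance(3)
  perm <- sample(ncol(inst$resp))
  spec1 <- buildDesign(inst$resp, cellCovariates = list(x = inst$xc),
                       sampleCovariates = cbind(g = inst$g))
  spec2 <- buildDesign(inst$resp[, perm], cellCovariates = list(x = inst$xc[, perm]),
                       sampleCovariates = cbind(g = inst$g[perm]))
  f1 <- remlFit(spec1); f2 <- remlFit(spec2)
  expect_equal(f1@beta, f2@beta, tolerance = 1e-6)
  expect_equal(blup(f1), blup(f2), tolerance = 1e-6)
  expect_equal(f1@sigma2u, f2@sigma2u, tolerance = 1e-6)
})
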