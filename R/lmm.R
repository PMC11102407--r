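#' Build a mixed-model design from a response matrix
#'
#' Flattens a species-by-sample response matrix species-major (all samples of
#' species 1, then species 2, ...) into the vector `y` of the model
#' `y = X beta + Z u + e`, and assembles the fixed-effects design `X` from an
#' intercept, optional per-cell covariates (species-by-sample matrices, e.g.
#' the matched 16S log_cpm value of the update module) and optional per-sample
#' covariates (replicated across species, e.g. PCs, group, timepoint). The
#' random-effects design `Z` is the per-species indicator implied by the
#' `species` factor.
#'
#' @param response species-by-sample numeric matrix (WGS log_cpm) or a
#'   `log_cpm` [AbundanceTable-class].
#' @param cellCovariates named list of species-by-sample matrices with the
#'   same dimnames as `response`; each contributes one column of `X`.
#' @param sampleCovariates matrix or data.frame with one row per sample
#'   (rownames = sample ids, aligned to `colnames(response)`); each column is
#'   replicated across species.
#' @param covMode `"diagonal"` (Sigma = sigma_u^2 I) or `"kernel"`
#'   (Sigma = sigma_u^2 K).
#' @param K fixed m-by-m symmetric PSD species correlation matrix (kernel
#'   mode only), dimnames = species.
#' @return A [MixedModelSpec-class].
#' @export
buildDesign <- function(response, cellCovariates = list(), sampleCovariates = NULL,
                        covMode = c("diagonal", "kernel"), K = NULL) {
  covMode <- match.arg(covMode)
  if (is(response, "AbundanceTable")) {
    if (response@unit != "log_cpm") stop("response must be in log_cpm unit")
    response <- abundanceValues(response)
  }
  response <- as.matrix(response)
  m <- nrow(response); n <- ncol(response)
  if (is.null(rownames(response)) || is.null(colnames(response)))
    stop("response needs species rownames and sample colnames")
  species_levels <- rownames(response)
  sample_ids <- colnames(response)
  y <- as.vector(t(response))                      # species-major
  species <- factor(rep(species_levels, each = n), levels = species_levels)
  samples <- rep(sample_ids, times = m)
  cols <- list(`(Intercept)` = rep(1, m * n))
  for (nm in names(cellCovariates)) {
    cm <- as.matrix(cellCovariates[[nm]])
    if (!all(dim(cm) == dim(response)))
      stop("misaligned cell covariate '", nm, "': dimensions differ from response")
    if (!is.null(rownames(cm)) && !identical(rownames(cm), species_levels))
      stop("misaligned cell covariate '", nm, "': species order differs")
    cols[[nm]] <- as.vector(t(cm))
  }
  if (!is.null(sampleCovariates)) {
    sc <- as.matrix(sampleCovariates)
    if (nrow(sc) != n) stop("sampleCovariates must have one row per sample")
    if (!is.null(rownames(sc)) && all(sample_ids %in% rownames(sc)))
      sc <- sc[sample_ids, , drop = FALSE]
    for (j in seq_len(ncol(sc)))
      cols[[colnames(sc)[j] %||% paste0("scov", j)]] <- rep(sc[, j], times = m)
  }
  X <- do.call(cbind, cols)
  if (qr(X)$rank < ncol(X))
    stop("fixed-effects design X is rank deficient")
  if (covMode == "kernel") {
    if (is.null(K)) stop("kernel mode requires K")
    K <- as.matrix(K)
    if (!is.null(rownames(K))) {
      if (!all(species_levels %in% rownames(K))) stop("K is missing species")
      K <- K[species_levels, species_levels]
    } else if (!all(dim(K) == c(m, m))) stop("K must be m x m")
  } else K <- matrix(0, 0, 0)
  new("MixedModelSpec", y = y, X = X, species = species, samples = samples,
      covMode = covMode, K = K)
}

#' @rdname designZ
#' @export
setMethod("designZ", "MixedModelSpec", function(spec) {
  n <- length(spec@y); m <- nlevels(spec@species)
  Z <- matrix(0, n, m, dimnames = list(NULL, levels(spec@species)))
  Z[cbind(seq_len(n), as.integer(spec@species))] <- 1
  Z
})

# Profiled REML evaluation at variance ratio gamma = sigma_u^2 / sigma_e^2.
# Uses the Woodbury identity W^-1 = I - gamma Z (I + gamma K D)^-1 K Z', with
# D = Z'Z = diag(species counts), so all linear algebra is m x m; Z is never
# materialized (Z'v is a rowsum by species, Zv an expansion).
.remlEval <- function(gamma, y, X, sp, K = NULL) {
  N <- length(y); p <- ncol(X)
  nj <- as.vector(table(sp))
  if (any(nj == 0)) stop("species level(s) with no observations")
  idx <- as.integer(sp)
  Ztv <- function(v) rowsum(v, idx)             # m x k
  if (is.null(K)) {
    b <- gamma / (1 + gamma * nj)
    Bmul <- function(Mv) Mv * b                 # diag(b) %*% Mv
    logdetW <- sum(log1p(gamma * nj))
  } else {
    A <- diag(nrow(K)) + gamma * K * rep(nj, each = nrow(K))  # I + gamma K D
    B <- gamma * solve(A, K)
    Bmul <- function(Mv) B %*% Mv
    dt <- determinant(A, logarithm = TRUE)
    logdetW <- as.numeric(dt$modulus)
  }
  Winv <- function(v) {
    v <- as.matrix(v)
    v - Bmul(Ztv(v))[idx, , drop = FALSE]
  }
  WiX <- Winv(X)
  XtWiX <- crossprod(X, WiX)
  XtWiX <- (XtWiX + t(XtWiX)) / 2
  Wiy <- Winv(y)
  beta <- solve(XtWiX, crossprod(X, Wiy))
  r <- y - X %*% beta
  Wir <- Winv(r)
  RSS <- sum(r * Wir)
  sigma2 <- RSS / (N - p)
  ll <- -0.5 * ((N - p) * (log(2 * pi * sigma2) + 1) + logdetW +
                  as.numeric(determinant(XtWiX, logarithm = TRUE)$modulus))
  uraw <- Ztv(Wir)                              # Z' W^-1 r, m x 1
  u <- if (is.null(K)) gamma * uraw else gamma * (K %*% uraw)
  list(loglik = ll, beta = drop(beta), sigma2 = sigma2,
       uHat = drop(u), XtWiXinv = solve(XtWiX))
}

#' Profiled REML log-likelihood
#'
#' Evaluates the REML log-likelihood of a [MixedModelSpec-class] at a given
#' `theta = sqrt(sigma_u^2 / sigma_e^2)`, with the fixed effects and the
#' residual variance profiled out analytically:
#' `-1/2 [ (N-p)(log(2 pi s2) + 1) + log|W| + log|X' W^-1 X| ]` where
#' `W = I + theta^2 Z K Z'` and `s2` is the profiled residual variance. This
#' equals the dense formula with explicit `V = Z Sigma Z' + sigma^2 I`.
#'
#' @param spec a [MixedModelSpec-class].
#' @param theta non-negative scalar.
#' @return scalar REML log-likelihood.
#' @export
remlLogLik <- function(spec, theta) {
  stopifnot(is(spec, "MixedModelSpec"), theta >= 0)
  K <- if (spec@covMode == "kernel") spec@K else NULL
  .remlEval(theta^2, spec@y, spec@X, spec@species, K)$loglik
}

#' Fit a linear mixed model by REML
#'
#' Maximizes the profiled REML log-likelihood over the single scale parameter
#' `theta = sqrt(sigma_u^2 / sigma_e^2)` (the Cholesky factor of the
#' random-effect covariance relative to the residual variance) by a
#' deterministic coarse log-grid followed by golden-section refinement
#' ([stats::optimize]). The boundary `theta = 0` (no species effect) is
#' handled explicitly: estimates are pinned at 0 when the boundary value is
#' not beaten. Returns BLUE fixed effects, BLUP random effects and variance
#' components.
#'
#' @param spec a [MixedModelSpec-class].
#' @param thetaMax upper bound of the search interval (default 100).
#' @param tol convergence tolerance on theta (default 1e-8).
#' @return A [FittedLMM-class].
#' @export
remlFit <- function(spec, thetaMax = 100, tol = 1e-8) {
  stopifnot(is(spec, "MixedModelSpec"))
  N <- length(spec@y); p <- ncol(spec@X)
  if (N <= p + 1) stop("not enough observations to fit the model")
  K <- if (spec@covMode == "kernel") spec@K else NULL
  f <- function(theta) .remlEval(theta^2, spec@y, spec@X, spec@species, K)$loglik
  grid <- c(0, 10^seq(-3, log10(thetaMax), length.out = 41))
  vals <- vapply(grid, f, numeric(1))
  i <- which.max(vals)
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
  theta <- grid[i]; ll <- vals[i]
  if (hi > lo) {
    opt <- optimize(f, c(lo, hi), maximum = TRUE, tol = tol)
    if (opt$objective > ll) { theta <- opt$maximum; ll <- opt$objective }
  }
  ll0 <- vals[1]
  if (ll0 >= ll - 1e-10 || theta < 1e-7) { theta <- 0; ll <- ll0 }
  e <- .remlEval(theta^2, spec@y, spec@X, spec@species, K)
  uhat <- setNames(as.numeric(e$uHat), levels(spec@species))
  new("FittedLMM",
      beta = setNames(e$beta, colnames(spec@X)),
      uHat = uhat,
      sigma2e = e$sigma2, sigma2u = theta^2 * e$sigma2, theta = theta,
      remlLogLik = e$loglik, converged = theta < thetaMax * 0.999,
      covMode = spec@covMode, K = spec@K,
      vcovBeta = e$sigma2 * e$XtWiXinv)
}

#' Implied random-effect covariance matrix
#'
#' Reconstructs `Sigma = sigma^2 Lambda_theta Lambda_theta'` for a fit:
#' `sigma_u^2 I` in diagonal mode, `sigma_u^2 K` in kernel mode.
#'
#' @param fit a [FittedLMM-class].
#' @return m-by-m covariance matrix.
#' @export
impliedSigma <- function(fit) {
  stopifnot(is(fit, "FittedLMM"))
  m <- length(fit@uHat)
  S <- if (fit@covMode == "kernel") fit@sigma2u * fit@K else fit@sigma2u * diag(m)
  dimnames(S) <- list(names(fit@uHat), names(fit@uHat))
  S
}

#' @rdname blup
#' @export
setMethod("blup", "FittedLMM", function(fit) fit@uHat)

#' Predict from a fitted mixed model
#'
#' Computes `y_hat = X_new beta_hat + u_hat[species]` for new rows. All
#' species must have been present at training time; unseen species raise an
#' error (the two-module predictor handles species routing upstream).
#'
#' @param object a [FittedLMM-class].
#' @param newX covariate matrix matching the training design's columns
#'   (intercept included).
#' @param species character/factor of length `nrow(newX)` naming each row's
#'   species.
#' @param ... ignored.
#' @return numeric vector of predictions (log_cpm scale).
#' @export
setMethod("predict", "FittedLMM", function(object, newX, species, ...) {
  newX <- as.matrix(newX)
  if (ncol(newX) != length(object@beta))
    stop("newX has ", ncol(newX), " columns; expected ", length(object@beta))
  species <- as.character(species)
  unseen <- setdiff(unique(species), names(object@uHat))
  if (length(unseen))
    stop("species not seen in training: ", paste(unseen, collapse = ", "))
  unname(drop(newX %*% object@beta) + object@uHat[species])
})

# Empty placeholder fit used when a module has no species to train on.
.emptyFit <- function() {
  new("FittedLMM", beta = numeric(0), uHat = numeric(0), sigma2e = NA_real_,
      sigma2u = NA_real_, theta = NA_real_, remlLogLik = NA_real_,
      converged = FALSE, covMode = "none", K = matrix(0, 0, 0),
      vcovBeta = matrix(0, 0, 0))
}
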