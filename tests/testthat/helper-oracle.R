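# Dense brute-force REML oracle, independent of the package's fitting path:
# explicit W = I + theta^2 Z K Z' inversion, profiled beta / sigma2, and a
# grid-refined 1-D theta search. Only suitable for small instances.

dense_reml_loglik <- function(theta, y, X, Z, K = NULL) {
  N <- length(y); p <- ncol(X); m <- ncol(Z)
  if (is.null(K)) K <- diag(m)
  W <- diag(N) + theta^2 * Z %*% K %*% t(Z)
  Wi <- solve(W)
  XtWiX <- t(X) %*% Wi %*% X
  beta <- solve(XtWiX, t(X) %*% Wi %*% y)
  r <- y - X %*% beta
  RSS <- drop(t(r) %*% Wi %*% r)
  s2 <- RSS / (N - p)
  ll <- -0.5 * ((N - p) * (log(2 * pi * s2) + 1) +
                  as.numeric(determinant(W, logarithm = TRUE)$modulus) +
                  as.numeric(determinant(XtWiX, logarithm = TRUE)$modulus))
  list(loglik = ll, beta = drop(beta), sigma2 = s2,
       uHat = drop(theta^2 * K %*% t(Z) %*% Wi %*% r))
}

dense_reml_fit <- function(y, X, Z, K = NULL, thetaMax = 100) {
  f <- function(th) dense_reml_loglik(th, y, X, Z, K)$loglik
  grid <- c(0, 10^seq(-3, log10(thetaMax), length.out = 61))
  vals <- vapply(grid, f, numeric(1))
  i <- which.max(vals)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  theta <- grid[i]; best <- vals[i]
  if (hi > lo) {
    opt <- optimize(f, c(lo, hi), maximum = TRUE, tol = 1e-10)
    if (opt$objective > best) { theta <- opt$maximum; best <- opt$objective }
  }
  if (vals[1] >= best - 1e-10 || theta < 1e-7) theta <- 0
  out <- dense_reml_loglik(theta, y, X, Z, K)
  out$theta <- theta
  out$sigma2u <- theta^2 * out$sigma2
  out
}

# Random small mixed-model instance (n samples x m species, species-major).
random_small_instance <- function(seed, kernel = FALSE) {
  set.seed(seed)
  n <- sample(3:8, 1); m <- sample(2:5, 1)
  species <- sprintf("sp%02d", seq_len(m))
  samples <- sprintf("S%02d", seq_len(n))
  xc <- matrix(rnorm(m * n), m, n, dimnames = list(species, samples))
  g <- rbinom(n, 1, 0.5)
  g[1:2] <- c(0L, 1L)   # keep the binary covariate non-degenerate at tiny n
  sigma_u <- sample(c(0, 0.5, 1.5), 1)
  u <- rnorm(m, 0, sigma_u)
  K <- NULL
  if (kernel) {
    A <- matrix(rnorm(m * m), m, m)
    K <- cov2cor(crossprod(A) + diag(m))
    dimnames(K) <- list(species, species)
    u <- drop(t(chol(K)) %*% rnorm(m)) * sigma_u
  }
  resp <- 0.5 + 0.9 * xc + outer(u, rep(1, n)) +
    outer(rep(1, m), 0.3 * g) + matrix(rnorm(m * n, 0, 0.7), m, n)
  dimnames(resp) <- list(species, samples)
  list(resp = resp, xc = xc, g = g, K = K, species = species, samples = samples)
}

# Assemble the dense design for an instance in the package's species-major
# flattening, without using package internals.
dense_design <- function(inst) {
  m <- nrow(inst$resp); n <- ncol(inst$resp)
  y <- as.vector(t(inst$resp))
  X <- cbind(1, as.vector(t(inst$xc)), rep(inst$g, times = m))
  Z <- matrix(0, n * m, m)
  Z[cbind(seq_len(n * m), rep(seq_len(m), each = n))] <- 1
  list(y = y, X = X, Z = Z)
}
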