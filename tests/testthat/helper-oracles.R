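# Independent reference implementations used as oracles. These are written
# scalar-by-scalar / by direct matrix algebra on purpose: they share no code
# path with the package internals they check.

# Brute-force method-of-moments IBD for one pair of dosage vectors, given
# per-SNP counted-allele frequencies. Solves the expected-IBS-count
# equations directly, then truncates and renormalises.
oracle_ibd_pair <- function(x1, x2, p) {
  keep <- !is.na(x1) & !is.na(x2)
  x1 <- x1[keep]; x2 <- x2[keep]; p <- p[keep]
  n0 <- n1 <- n2 <- 0
  e00 <- e10 <- e20 <- e11 <- e21 <- e22 <- 0
  for (k in seq_along(p)) {
    ibs <- 2 - abs(x1[k] - x2[k])
    if (ibs == 0) n0 <- n0 + 1
    if (ibs == 1) n1 <- n1 + 1
    if (ibs == 2) n2 <- n2 + 1
    pk <- p[k]; qk <- 1 - pk
    e00 <- e00 + 2 * pk^2 * qk^2
    e10 <- e10 + 4 * pk^3 * qk + 4 * pk * qk^3
    e20 <- e20 + pk^4 + qk^4 + 4 * pk^2 * qk^2
    e11 <- e11 + 2 * pk^2 * qk + 2 * pk * qk^2
    e21 <- e21 + pk^3 + qk^3 + pk^2 * qk + pk * qk^2
    e22 <- e22 + 1
  }
  # sequential bounded inversion, each probability truncated before use
  P0 <- min(n0 / e00, 1)
  P1 <- min(max((n1 - P0 * e10) / e11, 0), 1)
  P2 <- min(max((n2 - P0 * e20 - P1 * e21) / e22, 0), 1)
  P <- c(P0, P1, P2)
  P / sum(P)
}

# all-pairs oracle on a dosage matrix (monomorphic SNPs dropped first, as
# the estimator documents)
oracle_ibd <- function(X) {
  p <- colSums(X, na.rm = TRUE) / (2 * colSums(!is.na(X)))
  poly <- !is.na(p) & p > 0 & p < 1
  X <- X[, poly, drop = FALSE]
  p <- p[poly]
  n <- nrow(X)
  P0 <- P1 <- matrix(0, n, n)
  P2 <- diag(n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    est <- oracle_ibd_pair(X[i, ], X[j, ], p)
    P0[i, j] <- P0[j, i] <- est[1]
    P1[i, j] <- P1[j, i] <- est[2]
    P2[i, j] <- P2[j, i] <- est[3]
  }
  list(P0 = P0, P1 = P1, P2 = P2)
}

# Direct dense restricted log-likelihood of y ~ N(Xb, V), computed from the
# textbook definition with solve()/determinant() only.
oracle_reml_loglik <- function(y, X, V) {
  n <- length(y)
  p <- ncol(X)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtViX) %*% t(X) %*% Vi
  as.numeric(
    -0.5 * ((n - p) * log(2 * pi) +
              determinant(V, logarithm = TRUE)$modulus +
              determinant(XtViX, logarithm = TRUE)$modulus +
              t(y) %*% P %*% y))
}

# clamp a symmetric matrix's negative eigenvalues at zero (the projection
# fit_reml documents for method-of-moments kernels)
oracle_psd <- function(K) {
  e <- eigen(K, symmetric = TRUE)
  M <- e$vectors %*% (pmax(e$values, 0) * t(e$vectors))
  (M + t(M)) / 2
}

# MVN draw with covariance V through its symmetric square root
rmvn_sqrt <- function(n_draws, V) {
  e <- eigen(V, symmetric = TRUE)
  S <- e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
  S %*% matrix(rnorm(nrow(V) * n_draws), nrow(V), n_draws)
}

# small standard panel shared across tests
test_panel <- function(n = 40, m = 30, seed = 42) {
  simulate_genotypes(n, m, maf_range = c(0.1, 0.5), seed = seed)
}

test_kernels <- function(g) suppressWarnings(geneset_kernels(g))
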