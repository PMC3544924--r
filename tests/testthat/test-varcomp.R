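test_that("residual-only REML equals the n-1 sample variance", {
  set.seed(1)
  y <- rnorm(37, mean = 5)
  fit <- fit_reml(y, kernels = list())
  expect_equal(unname(fit$sigma2[["residual"]]), var(y), tolerance = 1e-12)
  X <- matrix(1, 37, 1)
  expect_equal(fit$loglik,
               oracle_reml_loglik(y, X, var(y) * diag(37)),
               tolerance = 1e-8)
})

test_that("reported log-likelihood matches the direct dense oracle", {
  g <- test_panel(n = 40, m = 30, seed = 42)
  ker <- test_kernels(g)
  Ks <- lapply(ker, function(k) oracle_psd(k$matrix))
  set.seed(43)
  y <- drop(rmvn_sqrt(1, 1.5 * Ks$A + 0.8 * Ks$D + diag(40)))
  X <- matrix(1, 40, 1)
  for (subset in list("A", "D", "AA", "AD", "DD",
                      c("A", "D"), c("AA", "DD"),
                      c("A", "D", "AA", "AD", "DD"))) {
    fit <- fit_reml(y, kernels = ker[subset])
    V <- diag(40) * fit$sigma2[["residual"]]
    for (nm in subset) V <- V + fit$sigma2[[nm]] * Ks[[nm]]
    expect_equal(fit$loglik, oracle_reml_loglik(y, X, V),
                 tolerance = 1e-6,
                 info = paste(subset, collapse = "+"))
  }
})

test_that("oracle agreement holds with categorical fixed effects", {
  g <- test_panel(n = 45, m = 30, seed = 52)
  ker <- test_kernels(g)
  covs <- data.frame(gender = rep(c("F", "M"), length.out = 45),
                     sire = rep(c("s1", "s2", "s3"), length.out = 45))
  set.seed(53)
  y <- rnorm(45) + as.integer(factor(covs$gender)) * 2
  fit <- fit_reml(y, kernels = ker["A"], covariates = covs)
  X <- model.matrix(~ gender + sire, data = covs)
  expect_identical(ncol(fit$X), 4L)  # intercept + 1 + 2 after ref dropping
  V <- fit$sigma2[["A"]] * oracle_psd(ker$A$matrix) +
    fit$sigma2[["residual"]] * diag(45)
  expect_equal(fit$loglik, oracle_reml_loglik(y, X, V), tolerance = 1e-6)
})

test_that("adding a kernel never decreases the restricted log-likelihood", {
  g <- test_panel(n = 45, m = 30, seed = 62)
  ker <- test_kernels(g)
  set.seed(63)
  y <- drop(rmvn_sqrt(1, 2 * oracle_psd(ker$A$matrix) + diag(45)))
  chain <- list(character(0), "A", c("A", "D"), c("A", "D", "AA"),
                c("A", "D", "AA", "AD", "DD"))
  ll <- vapply(chain, function(kn)
    fit_reml(y, kernels = ker[kn])$loglik, 0)
  expect_true(all(diff(ll) >= -1e-6))
})

test_that("variance components scale as c^2 and LRT statistics are invariant", {
  g <- test_panel(n = 40, m = 30, seed = 72)
  ker <- test_kernels(g)
  set.seed(73)
  y <- drop(rmvn_sqrt(1, oracle_psd(ker$A$matrix) + diag(40)))
  f1 <- fit_reml(y, kernels = ker["A"])
  n1 <- fit_reml(y, kernels = list())
  f2 <- fit_reml(3 * y, kernels = ker["A"])
  n2 <- fit_reml(3 * y, kernels = list())
  expect_equal(f2$sigma2, 9 * f1$sigma2, tolerance = 1e-5)
  s1 <- lrt(f1, n1)$statistic
  s2 <- lrt(f2, n2)$statistic
  expect_equal(s1, s2, tolerance = 1e-6)
})

test_that("single-kernel REML recovers known simulation parameters", {
  # quick version; the full 200-replicate recovery runs in the acceptance suite
  g <- simulate_genotypes(120, 40, seed = 82)
  A <- oracle_psd(test_kernels(g)$A$matrix)
  set.seed(83)
  Y <- rmvn_sqrt(40, 2 * A + diag(120))
  est <- apply(Y, 2, function(y)
    fit_reml(y, kernels = list(A = A))$sigma2)
  mse <- apply(est, 1, sd) / sqrt(ncol(Y))
  expect_lt(abs(mean(est["A", ]) - 2), 3 * mse["A"] + 1e-9)
  expect_lt(abs(mean(est["residual", ]) - 1), 3 * mse["residual"] + 1e-9)
})

test_that("boundary-mixture p-values match their reference distributions", {
  mixp <- cgsa:::mixture_pvalue
  expect_identical(mixp(0, 1), 1)
  # one component: half the chi-square(1) upper tail; 2.706 is the 0.90
  # quantile, so p should be 0.05
  expect_equal(mixp(2.706, 1), 0.05, tolerance = 1e-3)
  expect_equal(mixp(qchisq(0.9, 1), 1), 0.05, tolerance = 1e-12)
  # two components: compare with a large Monte-Carlo draw from the
  # 1/4 : 1/2 : 1/4 mixture of chi-square df 0, 1, 2
  set.seed(91)
  ndraw <- 1e6
  comp <- sample(0:2, ndraw, replace = TRUE, prob = c(0.25, 0.5, 0.25))
  draws <- numeric(ndraw)
  draws[comp == 1] <- rchisq(sum(comp == 1), 1)
  draws[comp == 2] <- rchisq(sum(comp == 2), 2)
  for (s in c(1, 3, 5)) {
    phat <- mean(draws >= s)
    se <- sqrt(phat * (1 - phat) / ndraw)
    expect_lt(abs(mixp(s, 2) - phat), 3 * se + 1e-9)
  }
})

test_that("lrt validates nesting and detects optimizer failures", {
  g <- test_panel(n = 30, m = 20, seed = 92)
  ker <- test_kernels(g)
  set.seed(93)
  y <- rnorm(30)
  fA <- fit_reml(y, kernels = ker["A"])
  f0 <- fit_reml(y, kernels = list())
  fD <- fit_reml(y, kernels = ker["D"])
  expect_error(lrt(fA, fD), "subset")
  expect_error(lrt(f0, fA), "subset")
  expect_error(lrt(fA, fit_reml(rnorm(30), kernels = list())), "share")
  # a null whose loglik exceeds the full signals a failed fit
  broken <- fA; broken$loglik <- f0$loglik - 1
  expect_error(lrt(broken, f0), "refit")
  # stat floored at zero gives p = 1
  res <- lrt(fA, f0)
  if (res$statistic == 0) expect_identical(res$p_value, 1)
  expect_gt(res$p_value, 0)
  expect_lte(res$p_value, 1)
})

test_that("gene-set test plan runs its nested comparisons and rejects duplicates", {
  g <- test_panel(n = 40, m = 30, seed = 102)
  ker <- test_kernels(g)
  tr <- simulate_additive_trait(g, 1:8, 0.5, seed = 103)
  res <- test_gene_set(tr$phenotype, ker)
  expect_identical(res$test, c("additive", "dominance", "epistasis"))
  expect_identical(res$n_components, c(1L, 3L)[c(1, 1, 2)])
  expect_true(all(res$p_value > 0 & res$p_value <= 1))
  fits <- attr(res, "fits")
  expect_identical(fits$epistasis$full$kernel_names,
                   c("A", "D", "AA", "AD", "DD"))
  expect_error(test_gene_set(tr$phenotype, ker,
                             plan = c("additive", "additive")), "duplicate")
  expect_error(test_gene_set(tr$phenotype, ker["A"], plan = "dominance"),
               "needs kernel")
})

test_that("a strong additive signal is detected nearly always", {
  g <- simulate_genotypes(300, 57, seed = 112)
  KA <- suppressWarnings(additive_matrix(estimate_ibd(g)))
  eA <- eigen(cgsa:::psd_project(KA$matrix), symmetric = TRUE)
  hits <- 0L
  nrep <- 100L
  for (r in seq_len(nrep)) {
    tr <- simulate_additive_trait(g, 1:15, 0.5, seed = 112 + r)
    res <- test_gene_set(tr$phenotype, list(A = KA), plan = "additive",
                         eigen_A = eA)
    hits <- hits + (res$p_value < 0.01)
  }
  expect_gte(hits / nrep, 0.95)
})

test_that("an identity kernel triggers a confounding warning", {
  set.seed(122)
  y <- rnorm(30)
  expect_warning(fit_reml(y, kernels = list(A = diag(30))), "confounded")
})
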