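power_result_new <- function(method, h2, alpha, n_reps, decisions, excluded,
                             qtn_idx, seed, scenario = NULL) {
  used <- !excluded
  pw <- mean(decisions[used])
  structure(list(method = method, h2 = h2, alpha = alpha,
                 n_reps = n_reps, n_used = sum(used),
                 n_excluded = sum(excluded),
                 power = pw,
                 se = sqrt(pw * (1 - pw) / sum(used)),
                 decisions = decisions, excluded = excluded,
                 qtn_idx = qtn_idx, seed = seed, scenario = scenario),
            class = "cgsa_power")
}

#' @export
print.cgsa_power <- function(x, ...) {
  cat(sprintf("cgsa_power [%s]: h2 = %g, alpha = %g, power = %.4f (SE %.4f, %d/%d replicates)\n",
              x$method, x$h2, x$alpha, x$power, x$se, x$n_used, x$n_reps))
  invisible(x)
}

# per-replicate seeds expand from the study seed by a simple counter;
# both methods of a paired comparison derive identical trait draws from it
replicate_seed <- function(seed, r) seed + r

sample_qtn <- function(g, n_qtn, seed) {
  m <- ncol(g$calls)
  if (n_qtn > m) stop("n_qtn exceeds the number of SNPs in the panel")
  set.seed(seed)
  sort(sample.int(m, n_qtn))
}

#' Power / type-I error of the gene-set variance-component test
#'
#' Replicate study of the set-level additive likelihood-ratio test: causal
#' QTNs are sampled once from the panel (seeded), then for each replicate a
#' trait is simulated at heritability `h2` (per-QTN effects redrawn
#' `N(0, 1)`; at `h2 = 0` pure noise), the additive-kernel mixed model is
#' fitted by REML against the residual-only null, and the boundary-mixture
#' LRT p-value is compared with `alpha`. Power is the proportion of
#' replicates rejected. The kernel and its eigendecomposition are computed
#' once and amortised across replicates.
#'
#' @param g a [genotype_matrix()] panel (fixed across replicates).
#' @param h2 trait heritability in `[0, 1)`; `0` estimates the type-I error.
#' @param n_qtn number of causal QTNs sampled from the panel.
#' @param alpha nominal significance level; a replicate is rejected when its
#'   p-value is `<= alpha`.
#' @param n_reps number of replicates.
#' @param seed study seed; QTN sampling and the per-replicate trait seeds
#'   derive from it, so re-running reproduces decisions bit-exactly.
#' @param kernel_A optional precomputed additive `cgsa_kinship` for the
#'   panel (computed from all panel SNPs when `NULL`).
#' @param covariates optional fixed-effect covariate `data.frame`.
#' @param mixture passed to [lrt()].
#' @return A `cgsa_power` object: method label, `power`, binomial `se`,
#'   per-replicate `decisions` and exclusion flags, QTN indices and seed.
#'   Replicates whose fits fail are excluded and counted (a warning is
#'   raised when exclusions exceed 1%).
#' @export
run_cgsa_power <- function(g, h2, n_qtn = 15L, alpha = 0.01, n_reps = 500L,
                           seed = 1L, kernel_A = NULL, covariates = NULL,
                           mixture = TRUE) {
  stopifnot(inherits(g, "cgsa_genotypes"))
  if (is.null(kernel_A)) {
    kernel_A <- suppressWarnings(
      additive_matrix(estimate_ibd(g)))
  }
  KA <- as_kernel_matrix(kernel_A)
  eigen_A <- eigen(KA, symmetric = TRUE)
  X <- build_design(nrow(g$calls), covariates)
  qtn <- sample_qtn(g, n_qtn, seed)
  null_fit_for <- function(y) fit_reml(y, kernels = list(), X = X)

  decisions <- logical(n_reps)
  excluded <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    res <- tryCatch({
      tr <- simulate_additive_trait(g, qtn, h2,
                                    seed = replicate_seed(seed, r))
      ff <- fit_reml(tr$phenotype, kernels = list(A = KA), X = X,
                     eigen_K = eigen_A)
      fn <- null_fit_for(tr$phenotype)
      if (!ff$converged || !fn$converged) stop("non-converged fit")
      lrt(ff, fn, mixture = mixture)$p_value
    }, error = function(e) NA_real_)
    if (is.na(res)) excluded[r] <- TRUE
    else decisions[r] <- res <= alpha
  }
  if (sum(excluded) > 0.01 * n_reps)
    warning(sum(excluded), " of ", n_reps,
            " replicates excluded for failed fits")
  power_result_new("CGSA", h2, alpha, n_reps, decisions, excluded, qtn, seed)
}

# two-sided p-values of per-SNP simple linear regressions, optionally after
# projecting out fixed covariates
single_snp_pvalues <- function(y, Z, X = NULL) {
  n <- length(y)
  dfres <- n - 2L
  if (!is.null(X) && ncol(X) > 1L) {
    qx <- qr(X)
    y <- qr.resid(qx, y)
    Z <- qr.resid(qx, Z)
    dfres <- n - ncol(X) - 1L
  } else {
    y <- y - mean(y)
    Z <- sweep(Z, 2L, colMeans(Z))
  }
  sy <- sqrt(sum(y^2))
  sz <- sqrt(colSums(Z^2))
  r <- drop(crossprod(Z, y)) / (sy * sz)
  r[sz == 0] <- NA                       # monomorphic column
  tval <- r * sqrt(dfres / pmax(1 - r^2, .Machine$double.eps))
  2 * stats::pt(-abs(tval), dfres)
}

#' Power of the single-SNP candidate-gene baseline
#'
#' The traditional candidate-gene comparator: each causal QTN is tested by a
#' single-SNP linear model (`trait ~ intercept + dosage`, plus any supplied
#' covariates). A QTN counts as detected when its (optionally
#' multiplicity-corrected) p-value is `<= alpha`; a replicate's score is the
#' proportion of its QTNs detected, and power is the mean score over
#' replicates. Traits are regenerated from the same study seed as
#' [run_cgsa_power()], so runs with a shared seed form a paired comparison
#' on identical phenotypes.
#'
#' @inheritParams run_cgsa_power
#' @param correction multiple-testing correction applied across the QTNs of
#'   a replicate, any method of [stats::p.adjust()] (default `"none"`,
#'   testing each QTN at the nominal level).
#' @param score `"proportion"` (default: fraction of QTNs detected per
#'   replicate) or `"any"` (replicate counts as a detection if any QTN
#'   passes).
#' @return A `cgsa_power` object with method label `"single-SNP"`; its
#'   `decisions` element holds the per-replicate scores. Monomorphic QTNs
#'   are excluded from the denominator with a warning.
#' @export
run_baseline_power <- function(g, h2, n_qtn = 15L, alpha = 0.01,
                               n_reps = 500L, seed = 1L, covariates = NULL,
                               correction = "none",
                               score = c("proportion", "any")) {
  stopifnot(inherits(g, "cgsa_genotypes"))
  score <- match.arg(score)
  X <- build_design(nrow(g$calls), covariates)
  qtn <- sample_qtn(g, n_qtn, seed)
  Z <- g$calls[, qtn, drop = FALSE]
  storage.mode(Z) <- "double"
  mono <- apply(Z, 2L, function(z) stats::var(z) == 0)
  if (any(mono)) {
    warning(sum(mono), " monomorphic QTN(s) excluded from the detection denominator")
    Z <- Z[, !mono, drop = FALSE]
  }
  scores <- numeric(n_reps)
  excluded <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    tr <- simulate_additive_trait(g, qtn, h2, seed = replicate_seed(seed, r))
    pv <- single_snp_pvalues(tr$phenotype, Z, X)
    padj <- stats::p.adjust(pv, method = correction)
    det <- padj <= alpha
    scores[r] <- if (score == "any") any(det, na.rm = TRUE)
                 else mean(det, na.rm = TRUE)
  }
  power_result_new("single-SNP", h2, alpha, n_reps, scores, excluded, qtn,
                   seed)
}

#' Tabulate power results across methods and heritability levels
#'
#' @param results a list of `cgsa_power` objects (all at the same `alpha`).
#' @return A `data.frame` with columns `method`, `h2`, `alpha`, `reps`,
#'   `power`, `se`, sorted by `(method, h2)`.
#' @seealso [plot_power()]
#' @export
summarize_power <- function(results) {
  if (inherits(results, "cgsa_power")) results <- list(results)
  if (length(results) == 0L) stop("no power results to summarise")
  stopifnot(all(vapply(results, inherits, TRUE, "cgsa_power")))
  alphas <- vapply(results, `[[`, 0, "alpha")
  if (length(unique(alphas)) > 1L)
    stop("mixed alpha values in one summary table: ",
         paste(unique(alphas), collapse = ", "))
  tab <- do.call(rbind, lapply(results, function(x)
    data.frame(method = x$method, h2 = x$h2, alpha = x$alpha,
               reps = x$n_used, power = x$power, se = x$se,
               stringsAsFactors = FALSE)))
  tab <- tab[order(tab$method, tab$h2), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Line plot of power against heritability, one line per method
#'
#' @param tab a summary table from [summarize_power()].
#' @return A `ggplot` object (requires the suggested ggplot2 package).
#' @export
plot_power <- function(tab) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_power needs the ggplot2 package")
  h2 <- power <- method <- se <- NULL  # NSE column bindings
  ggplot2::ggplot(tab, ggplot2::aes(x = h2, y = power, colour = method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = pmax(0, power - se),
                                        ymax = pmin(1, power + se)),
                           width = 0.01) +
    ggplot2::labs(x = "heritability", y = "statistical power",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Paired power study: gene-set test versus single-SNP baseline
#'
#' Runs [run_cgsa_power()] and [run_baseline_power()] on the same panel over
#' a grid of heritability levels with shared seeds (identical simulated
#' traits per replicate), and returns both the raw results and the tidy
#' summary.
#'
#' @inheritParams run_cgsa_power
#' @param h2_levels numeric vector of heritabilities.
#' @param correction passed to [run_baseline_power()].
#' @return List with `results` (list of `cgsa_power`) and `table` (from
#'   [summarize_power()]).
#' @export
run_power_study <- function(g, h2_levels = c(0, 0.05, 0.1, 0.25, 0.5),
                            n_qtn = 15L, alpha = 0.01, n_reps = 500L,
                            seed = 1L, covariates = NULL,
                            correction = "none") {
  kernel_A <- suppressWarnings(additive_matrix(estimate_ibd(g)))
  results <- list()
  for (h2 in h2_levels) {
    results[[length(results) + 1L]] <-
      run_cgsa_power(g, h2, n_qtn = n_qtn, alpha = alpha, n_reps = n_reps,
                     seed = seed, kernel_A = kernel_A,
                     covariates = covariates)
    results[[length(results) + 1L]] <-
      run_baseline_power(g, h2, n_qtn = n_qtn, alpha = alpha,
                         n_reps = n_reps, seed = seed,
                         covariates = covariates, correction = correction)
  }
  list(results = results, table = summarize_power(results))
}
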