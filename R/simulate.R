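#' Simulate a Hardy-Weinberg genotype panel
#'
#' Draws an `n x m` dosage matrix of unlinked biallelic SNPs: each SNP's
#' counted-allele frequency is drawn uniformly from `maf_range` and each
#' individual's dosage is `Binomial(2, p)` (Hardy-Weinberg equilibrium,
#' linkage equilibrium). The generator emulates the kind of panel a gene-set
#' study works with - by default 57 SNPs as in a single signalling pathway -
#' without linkage disequilibrium structure.
#'
#' @param n number of individuals (>= 2).
#' @param m number of SNPs (>= 1).
#' @param maf_range length-2 numeric in `(0, 0.5]`, allele-frequency draw
#'   range (default `c(0.05, 0.5)`).
#' @param seed optional integer; when supplied the draw is reproducible.
#' @param chrom chromosome label for the synthetic map positions.
#' @return A [genotype_matrix()] with individuals `ind0001...` and SNPs
#'   `snp0001...`; synthetic positions 1e6 apart. True allele frequencies
#'   are attached as attribute `"true_maf"`.
#' @export
simulate_genotypes <- function(n, m, maf_range = c(0.05, 0.5), seed = NULL,
                               chrom = "1") {
  if (n < 2L) stop("n must be >= 2")
  if (m < 1L) stop("m must be >= 1")
  if (length(maf_range) != 2L || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2])
    stop("maf_range must lie within (0, 0.5] with min <= max")
  if (!is.null(seed)) set.seed(seed)
  p <- stats::runif(m, maf_range[1], maf_range[2])
  calls <- matrix(stats::rbinom(n * m, 2L, rep(p, each = n)), n, m)
  ids <- sprintf("ind%04d", seq_len(n))
  snps <- sprintf("snp%04d", seq_len(m))
  g <- genotype_matrix(calls, ids, snps,
                       positions = data.frame(snp_id = snps, chrom = chrom,
                                              pos = seq_len(m) * 1000000L))
  attr(g, "true_maf") <- stats::setNames(p, snps)
  g
}

sim_trait_new <- function(phenotype, genetic_value, sigma2_a, sigma2_e,
                          seed, qtn_idx) {
  structure(list(phenotype = phenotype, genetic_value = genetic_value,
                 sigma2_a = sigma2_a, sigma2_e = sigma2_e,
                 seed = seed, qtn_idx = qtn_idx),
            class = "cgsa_sim_trait")
}

#' @export
print.cgsa_sim_trait <- function(x, ...) {
  cat(sprintf(paste0("cgsa_sim_trait: n = %d, realized sigma2_a = %.4f, ",
                     "residual variance parameter = %.4f\n"),
              length(x$phenotype), x$sigma2_a, x$sigma2_e))
  invisible(x)
}

#' Simulate an additive polygenic trait at a target heritability
#'
#' Each causal QTN gets an additive effect drawn from `N(0, 1)` (redrawn per
#' call unless `effects` is supplied); the genetic value is the dosage-
#' weighted sum over QTNs. The residual variance is scaled to the realized
#' (in-sample) additive genetic variance `s2_a` so that the trait attains
#' the target heritability: `s2_e = s2_a * (1 - h2) / h2`. At `h2 = 0` the
#' ratio is undefined; the genetic contribution is removed entirely and the
#' trait is pure `N(0, 1)` noise (any positive residual scale is equivalent
#' under the scale equivariance of the downstream tests).
#'
#' @param g a [genotype_matrix()] object.
#' @param qtn_idx integer column indices (or SNP ids) of the causal QTNs.
#' @param h2 target narrow-sense heritability in `[0, 1)`.
#' @param seed optional integer for reproducibility.
#' @param effects optional fixed numeric vector of per-QTN additive effects
#'   (default: redrawn `N(0, 1)` per call).
#' @return A `cgsa_sim_trait`: list with `phenotype`, `genetic_value`,
#'   `sigma2_a` (realized additive variance), `sigma2_e` (residual variance
#'   parameter), `seed`, `qtn_idx`.
#' @export
simulate_additive_trait <- function(g, qtn_idx, h2, seed = NULL,
                                    effects = NULL) {
  stopifnot(inherits(g, "cgsa_genotypes"))
  if (h2 < 0 || h2 >= 1) stop("h2 must be in [0, 1)")
  if (is.character(qtn_idx)) qtn_idx <- match(qtn_idx, g$snp_ids)
  if (length(qtn_idx) == 0L || anyNA(qtn_idx) ||
      any(qtn_idx < 1L | qtn_idx > ncol(g$calls)))
    stop("qtn_idx must be non-empty valid SNP columns")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(g$calls)

  if (h2 == 0) {
    ph <- stats::rnorm(n, 0, 1)
    return(sim_trait_new(ph, rep(0, n), 0, 1, seed, qtn_idx))
  }
  beta <- if (is.null(effects)) stats::rnorm(length(qtn_idx), 0, 1)
          else as.numeric(effects)
  if (length(beta) != length(qtn_idx))
    stop("effects must have one value per QTN")
  Z <- g$calls[, qtn_idx, drop = FALSE]
  if (anyNA(Z)) stop("QTN columns contain missing calls; impute or drop first")
  gv <- drop(Z %*% beta)
  s2a <- stats::var(gv)
  if (s2a == 0)
    stop("all QTNs monomorphic: realized additive variance is zero")
  s2e <- s2a * (1 - h2) / h2
  ph <- gv + stats::rnorm(n, 0, sqrt(s2e))
  sim_trait_new(ph, gv, s2a, s2e, seed, qtn_idx)
}

#' Simulate a trait with additive, dominance and epistatic effects
#'
#' The genetic value of individual `i` is the sum of three parts: additive
#' `sum_j a_j * dosage_ij`; dominance `sum_j d_j * [dosage_ij == 1]`; and
#' epistatic `sum_pairs e_p * [heterozygous at both pair members]` - a pair's
#' effect is expressed only when an individual is heterozygous at both of
#' its QTNs. The residual is `N(0, residual_var)`.
#'
#' @param g a [genotype_matrix()] object.
#' @param effects `data.frame` with columns `snp_id`, `additive`,
#'   `dominance`, one row per causal QTN.
#' @param pairs optional `data.frame` with columns `snp1`, `snp2`, `effect`;
#'   both members must appear in `effects$snp_id` and pairs must not share
#'   members.
#' @param residual_var residual variance (default 10).
#' @param seed optional integer for reproducibility.
#' @return A `cgsa_sim_trait`; `sigma2_a` holds the realized variance of the
#'   additive part alone, and the realized total genetic variance is
#'   attached as attribute `"sigma2_g"`.
#' @export
simulate_full_trait <- function(g, effects, pairs = NULL, residual_var = 10,
                                seed = NULL) {
  stopifnot(inherits(g, "cgsa_genotypes"))
  req <- c("snp_id", "additive", "dominance")
  if (!all(req %in% names(effects)))
    stop("effects needs columns: ", paste(req, collapse = ", "))
  idx <- match(as.character(effects$snp_id), g$snp_ids)
  if (anyNA(idx))
    stop("effect-table SNPs absent from genotypes: ",
         paste(effects$snp_id[is.na(idx)], collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  Z <- g$calls[, idx, drop = FALSE]
  if (anyNA(Z)) stop("QTN columns contain missing calls; impute or drop first")
  H <- (Z == 1L) * 1
  g_add <- drop(Z %*% effects$additive)
  g_dom <- drop(H %*% effects$dominance)
  g_epi <- rep(0, nrow(Z))
  if (!is.null(pairs) && nrow(pairs) > 0L) {
    reqp <- c("snp1", "snp2", "effect")
    if (!all(reqp %in% names(pairs)))
      stop("pairs needs columns: ", paste(reqp, collapse = ", "))
    members <- c(as.character(pairs$snp1), as.character(pairs$snp2))
    bad <- setdiff(members, as.character(effects$snp_id))
    if (length(bad))
      stop("pair member(s) not in the QTN effect table: ",
           paste(unique(bad), collapse = ", "))
    if (anyDuplicated(members))
      stop("epistatic pairs must not share members")
    for (r in seq_len(nrow(pairs))) {
      j1 <- match(as.character(pairs$snp1[r]), as.character(effects$snp_id))
      j2 <- match(as.character(pairs$snp2[r]), as.character(effects$snp_id))
      g_epi <- g_epi + pairs$effect[r] * (H[, j1] * H[, j2])
    }
  }
  gv <- g_add + g_dom + g_epi
  ph <- gv + stats::rnorm(nrow(Z), 0, sqrt(residual_var))
  out <- sim_trait_new(ph, gv, stats::var(g_add), residual_var, seed, idx)
  attr(out, "sigma2_g") <- stats::var(gv)
  attr(out, "components") <- list(additive = g_add, dominance = g_dom,
                                  epistatic = g_epi)
  out
}

#' Default epistatic-scenario effect table
#'
#' Loads the packaged synthetic effect table used by the mixed
#' additive/dominance/epistasis simulation scenario: 13 causal QTNs with
#' additive effects drawn from `N(0, 1)`, dominance effects from
#' `N(0, 0.5)`, and three non-overlapping heterozygote-by-heterozygote pairs
#' with effects of magnitude 1. The values are synthetic stand-ins (drawn
#' once and frozen in `inst/extdata/`), overridable by any TSV with the same
#' columns.
#'
#' @return List with `effects` (data.frame: `snp_id`, `additive`,
#'   `dominance`) and `pairs` (data.frame: `pair_id`, `snp1`, `snp2`,
#'   `effect`).
#' @export
default_epistatic_effects <- function() {
  eff <- utils::read.delim(
    system.file("extdata", "sim_effects_synthetic.tsv", package = "cgsa"),
    comment.char = "#", stringsAsFactors = FALSE)
  prs <- utils::read.delim(
    system.file("extdata", "sim_pairs_synthetic.tsv", package = "cgsa"),
    comment.char = "#", stringsAsFactors = FALSE)
  list(effects = eff, pairs = prs)
}
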