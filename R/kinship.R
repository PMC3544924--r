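#' Method-of-moments IBD estimation for all pairs
#'
#' Estimates, for every unordered pair of individuals, the probabilities
#' `P0`, `P1`, `P2` of sharing 0, 1 or 2 alleles identical by descent (IBD),
#' using the PLINK-style method of moments: observed counts of
#' identity-by-state (IBS) 0/1/2 across SNPs are equated to their
#' expectations given IBD state and in-sample allele frequencies, and the
#' resulting triangular system is solved pair by pair. Raw estimates can
#' fall outside `[0, 1]`; each is truncated to `[0, 1]` before entering the
#' next moment equation and the triple is then renormalised onto the
#' probability simplex.
#'
#' Only SNPs non-missing in both members of a pair contribute to that pair's
#' moment equations (pairwise-complete handling). Monomorphic SNPs carry no
#' IBS information and are skipped with a warning. Allele frequencies are
#' estimated from the sample itself.
#'
#' @param g a [genotype_matrix()] object with at least 2 individuals.
#' @param snp_subset optional character vector of SNP ids (or integer column
#'   indices) restricting estimation to a gene set's SNPs.
#' @param min_informative pairs with fewer informative SNPs than this are
#'   flagged low-confidence (default 10).
#' @return An object of class `cgsa_ibd`: list with `P0`, `P1`, `P2`
#'   (symmetric `n x n` matrices, diagonal `P2 = 1`), `n_informative`
#'   (matrix of per-pair informative SNP counts), `low_confidence` (logical
#'   matrix) and `individual_ids`.
#' @seealso [additive_matrix()], [dominance_matrix()]
#' @export
estimate_ibd <- function(g, snp_subset = NULL, min_informative = 10L) {
  stopifnot(inherits(g, "cgsa_genotypes"))
  X <- g$calls
  if (!is.null(snp_subset)) {
    if (is.character(snp_subset)) {
      missing_ids <- setdiff(snp_subset, g$snp_ids)
      if (length(missing_ids))
        stop("snp_subset ids absent from genotypes: ",
             paste(missing_ids, collapse = ", "))
      X <- X[, snp_subset, drop = FALSE]
    } else X <- X[, snp_subset, drop = FALSE]
  }
  n <- nrow(X)
  if (n < 2L) stop("need at least 2 individuals")

  p <- colSums(X, na.rm = TRUE) / (2 * colSums(!is.na(X)))
  mono <- !is.na(p) & (p <= 0 | p >= 1)
  mono[is.na(p)] <- TRUE
  if (any(mono)) {
    warning(sum(mono), " monomorphic/uninformative SNP(s) skipped in IBD estimation")
    X <- X[, !mono, drop = FALSE]
    p <- p[!mono]
  }
  m <- ncol(X)
  if (m == 0L) stop("no polymorphic SNPs available for IBD estimation")
  q <- 1 - p

  # per-SNP expected IBS-state probabilities conditional on IBD state
  e0_ibd0 <- 2 * p^2 * q^2
  e1_ibd0 <- 4 * p^3 * q + 4 * p * q^3
  e2_ibd0 <- p^4 + q^4 + 4 * p^2 * q^2
  e1_ibd1 <- 2 * p * q                 # 2p^2q + 2pq^2
  e2_ibd1 <- p^2 + q^2                 # p^3 + q^3 + p^2 q + p q^2

  M <- !is.na(X)                        # observed indicator
  storage.mode(M) <- "double"
  H0 <- (!is.na(X) & X == 0L); storage.mode(H0) <- "double"
  H1 <- (!is.na(X) & X == 1L); storage.mode(H1) <- "double"
  H2 <- (!is.na(X) & X == 2L); storage.mode(H2) <- "double"

  n_valid <- M %*% t(M)
  N0 <- H0 %*% t(H2) + H2 %*% t(H0)    # opposite homozygotes
  N2 <- H0 %*% t(H0) + H1 %*% t(H1) + H2 %*% t(H2)
  N1 <- n_valid - N0 - N2

  pairsum <- function(e) (M * rep(e, each = n)) %*% t(M)
  E0_0 <- pairsum(e0_ibd0)
  E1_0 <- pairsum(e1_ibd0)
  E2_0 <- pairsum(e2_ibd0)
  E1_1 <- pairsum(e1_ibd1)
  E2_1 <- pairsum(e2_ibd1)

  # sequential bounded inversion: each estimate is truncated to [0, 1]
  # before it enters the next moment equation (PLINK's bounded behaviour),
  # then the triple is renormalised onto the simplex
  P0 <- pmin(N0 / E0_0, 1)
  P1 <- pmin(pmax((N1 - P0 * E1_0) / E1_1, 0), 1)
  P2 <- pmin(pmax((N2 - P0 * E2_0 - P1 * E2_1) / n_valid, 0), 1)
  s <- P0 + P1 + P2
  s[s == 0] <- 1
  P0 <- P0 / s; P1 <- P1 / s; P2 <- P2 / s

  diag(P0) <- 0; diag(P1) <- 0; diag(P2) <- 1
  low <- n_valid < min_informative
  diag(low) <- FALSE
  ids <- rownames(X)
  dimnames(P0) <- dimnames(P1) <- dimnames(P2) <-
    dimnames(n_valid) <- dimnames(low) <- list(ids, ids)
  structure(list(P0 = P0, P1 = P1, P2 = P2,
                 n_informative = n_valid, low_confidence = low,
                 individual_ids = ids),
            class = "cgsa_ibd")
}

#' @export
print.cgsa_ibd <- function(x, ...) {
  n <- length(x$individual_ids)
  off <- upper.tri(x$P2)
  cat(sprintf("cgsa_ibd: %d individuals, %d pairs\n", n, sum(off)))
  cat(sprintf("  mean off-diagonal pi-hat: %.4f\n",
              mean((x$P2 + 0.5 * x$P1)[off])))
  if (any(x$low_confidence[off]))
    cat(sprintf("  low-confidence pairs: %d\n", sum(x$low_confidence[off])))
  invisible(x)
}

#' @method as.data.frame cgsa_ibd
#' @export
as.data.frame.cgsa_ibd <- function(x, ...) {
  idx <- which(upper.tri(x$P0), arr.ind = TRUE)
  data.frame(id1 = x$individual_ids[idx[, 1]],
             id2 = x$individual_ids[idx[, 2]],
             P0 = x$P0[idx], P1 = x$P1[idx], P2 = x$P2[idx],
             n_informative = x$n_informative[idx],
             low_confidence = x$low_confidence[idx],
             stringsAsFactors = FALSE)
}

kinship_new <- function(mat, kind, ids) {
  dimnames(mat) <- list(ids, ids)
  structure(list(kind = kind, matrix = mat, individual_ids = ids),
            class = "cgsa_kinship")
}

#' @export
print.cgsa_kinship <- function(x, ...) {
  off <- upper.tri(x$matrix)
  cat(sprintf("cgsa_kinship (%s): %d x %d, mean off-diagonal %.4f\n",
              x$kind, nrow(x$matrix), ncol(x$matrix),
              mean(x$matrix[off])))
  invisible(x)
}

#' Additive relationship matrix from pairwise IBD estimates
#'
#' Off-diagonal entries are PLINK's pi-hat, `P(IBD=2) + 0.5 * P(IBD=1)`. The
#' diagonal is set to the self-relationship convention for an outbred
#' population, `A[i,i] = 1` (pairwise IBD output carries no self terms and
#' inbreeding is ignored); override via `diagonal`.
#'
#' @param ibd a [estimate_ibd()] result.
#' @param diagonal self-relationship value (default 1).
#' @return A `cgsa_kinship` object of kind `"A"`.
#' @export
additive_matrix <- function(ibd, diagonal = 1) {
  stopifnot(inherits(ibd, "cgsa_ibd"))
  A <- ibd$P2 + 0.5 * ibd$P1
  diag(A) <- diagonal
  kinship_new(A, "A", ibd$individual_ids)
}

#' Dominance relationship matrix from pairwise IBD estimates
#'
#' Off-diagonal entries are `P(IBD=2)`, the probability both alleles are
#' shared identical by descent; diagonal per the same self-relationship
#' convention as [additive_matrix()].
#'
#' @inheritParams additive_matrix
#' @return A `cgsa_kinship` object of kind `"D"`.
#' @export
dominance_matrix <- function(ibd, diagonal = 1) {
  stopifnot(inherits(ibd, "cgsa_ibd"))
  D <- ibd$P2
  diag(D) <- diagonal
  kinship_new(D, "D", ibd$individual_ids)
}

#' Epistatic kernels as Hadamard products
#'
#' Builds the additive-by-additive, additive-by-dominance and
#' dominance-by-dominance relationship matrices as elementwise products of
#' the additive and dominance matrices: `AA = A * A`, `AD = A * D`,
#' `DD = D * D`.
#'
#' @param A,D `cgsa_kinship` objects of kinds `"A"` and `"D"` over the same
#'   individuals in the same order.
#' @return Named list of `cgsa_kinship` objects `AA`, `AD`, `DD`.
#' @export
hadamard_kernels <- function(A, D) {
  stopifnot(inherits(A, "cgsa_kinship"), inherits(D, "cgsa_kinship"))
  if (!identical(dim(A$matrix), dim(D$matrix)) ||
      !identical(A$individual_ids, D$individual_ids))
    stop("A and D must share dimension and individual order")
  ids <- A$individual_ids
  list(AA = kinship_new(A$matrix * A$matrix, "AA", ids),
       AD = kinship_new(A$matrix * D$matrix, "AD", ids),
       DD = kinship_new(D$matrix * D$matrix, "DD", ids))
}

#' Build all five gene-set kernels from genotypes
#'
#' Convenience wrapper running [estimate_ibd()], [additive_matrix()],
#' [dominance_matrix()] and [hadamard_kernels()] in one call.
#'
#' @inheritParams estimate_ibd
#' @return Named list of `cgsa_kinship` objects `A`, `D`, `AA`, `AD`, `DD`.
#' @export
geneset_kernels <- function(g, snp_subset = NULL, min_informative = 10L) {
  ibd <- estimate_ibd(g, snp_subset = snp_subset,
                      min_informative = min_informative)
  A <- additive_matrix(ibd)
  D <- dominance_matrix(ibd)
  c(list(A = A, D = D), hadamard_kernels(A, D))
}

#' Write a kinship matrix as a square TSV
#'
#' Square matrix with a header row and leading column of individual IDs,
#' interoperable with common REML tools.
#'
#' @param k a `cgsa_kinship` object.
#' @param path output path.
#' @export
write_kinship <- function(k, path) {
  stopifnot(inherits(k, "cgsa_kinship"))
  tab <- data.frame(id = k$individual_ids, k$matrix, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(k)
}

#' Read a square kinship TSV written by [write_kinship()]
#'
#' @param path input path.
#' @param kind kernel label to attach (`"A"`, `"D"`, `"AA"`, `"AD"`, `"DD"`).
#' @return A `cgsa_kinship` object.
#' @export
read_kinship <- function(path, kind = "A") {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  ids <- as.character(tab[[1L]])
  mat <- as.matrix(tab[, -1L, drop = FALSE])
  if (!identical(colnames(mat), ids))
    stop("kinship TSV header does not match its id column")
  storage.mode(mat) <- "double"
  kinship_new(mat, kind, ids)
}

#' Import pairwise IBD probabilities from a PLINK .genome file
#'
#' Reads the whitespace-delimited `.genome` output of PLINK's `--genome`
#' (columns `IID1`, `IID2`, `Z0`, `Z1`, `Z2`) into a `cgsa_ibd` object so
#' externally computed estimates can feed [additive_matrix()] and
#' [dominance_matrix()].
#'
#' @param path path to the `.genome` file.
#' @return A `cgsa_ibd` object (informative-SNP counts unavailable; set to
#'   `NA`).
#' @export
read_plink_genome <- function(path) {
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  req <- c("IID1", "IID2", "Z0", "Z1", "Z2")
  if (!all(req %in% names(tab)))
    stop(".genome file needs columns: ", paste(req, collapse = ", "))
  ids <- unique(c(tab$IID1, tab$IID2))
  n <- length(ids)
  P0 <- P1 <- matrix(0, n, n, dimnames = list(ids, ids))
  P2 <- diag(n); dimnames(P2) <- list(ids, ids)
  i <- match(tab$IID1, ids); j <- match(tab$IID2, ids)
  P0[cbind(i, j)] <- P0[cbind(j, i)] <- tab$Z0
  P1[cbind(i, j)] <- P1[cbind(j, i)] <- tab$Z1
  P2[cbind(i, j)] <- P2[cbind(j, i)] <- tab$Z2
  diag(P2) <- 1
  nv <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  low <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  structure(list(P0 = P0, P1 = P1, P2 = P2, n_informative = nv,
                 low_confidence = low, individual_ids = ids),
            class = "cgsa_ibd")
}
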