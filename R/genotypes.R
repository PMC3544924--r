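#' Construct a genotype matrix object
#'
#' A `cgsa_genotypes` object stores allele-dosage genotype calls for a panel
#' of individuals: an `n x m` integer matrix coded 0/1/2 as the count of the
#' designated counted allele, with `NA` as the explicit missing-call sentinel
#' (never silently treated as zero). Row and column identity is carried by
#' unique individual and SNP identifiers; optional per-SNP map positions
#' (chromosome label, 1-based base-pair position) support SNP-to-gene
#' assignment.
#'
#' @param calls integer matrix, individuals in rows, SNPs in columns; values
#'   0, 1, 2 or `NA` (missing).
#' @param individual_ids character vector of unique individual identifiers,
#'   one per row.
#' @param snp_ids character vector of unique SNP identifiers, one per column.
#' @param positions optional `data.frame` with columns `snp_id`, `chrom`
#'   (character) and `pos` (1-based integer), one row per SNP.
#' @return An object of class `cgsa_genotypes` with elements `calls`,
#'   `individual_ids`, `snp_ids` and `positions`.
#' @examples
#' g <- genotype_matrix(matrix(c(0L, 1L, 2L, 1L), 2, 2),
#'                      individual_ids = c("a", "b"),
#'                      snp_ids = c("s1", "s2"))
#' allele_freq(g)
#' @export
genotype_matrix <- function(calls, individual_ids, snp_ids, positions = NULL) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (nrow(calls) != length(individual_ids))
    stop("number of rows of 'calls' must equal length of 'individual_ids'")
  if (ncol(calls) != length(snp_ids))
    stop("number of columns of 'calls' must equal length of 'snp_ids'")
  individual_ids <- as.character(individual_ids)
  snp_ids <- as.character(snp_ids)
  if (anyDuplicated(individual_ids))
    stop("individual_ids must be unique")
  if (anyDuplicated(snp_ids))
    stop("snp_ids must be unique")
  bad <- !is.na(calls) & !(calls %in% 0:2)
  if (any(bad))
    stop("genotype calls must be 0, 1, 2 or NA; found ",
         paste(unique(calls[bad]), collapse = ", "))
  if (!is.null(positions)) {
    positions <- as.data.frame(positions)
    req <- c("snp_id", "chrom", "pos")
    if (!all(req %in% names(positions)))
      stop("'positions' needs columns: ", paste(req, collapse = ", "))
    positions$snp_id <- as.character(positions$snp_id)
    positions$chrom <- as.character(positions$chrom)
    positions$pos <- as.integer(positions$pos)
    if (!setequal(positions$snp_id, snp_ids))
      stop("'positions' must cover exactly the SNPs in 'snp_ids'")
    positions <- positions[match(snp_ids, positions$snp_id), , drop = FALSE]
    rownames(positions) <- NULL
    if (any(positions$pos < 1L, na.rm = TRUE))
      stop("SNP positions must be positive (1-based)")
  }
  dimnames(calls) <- list(individual_ids, snp_ids)
  structure(
    list(calls = calls, individual_ids = individual_ids,
         snp_ids = snp_ids, positions = positions),
    class = "cgsa_genotypes")
}

#' @export
print.cgsa_genotypes <- function(x, ...) {
  cat(sprintf("cgsa_genotypes: %d individuals x %d SNPs\n",
              nrow(x$calls), ncol(x$calls)))
  nm <- sum(is.na(x$calls))
  cat(sprintf("  missing calls: %d (%.2f%%)\n", nm, 100 * nm / length(x$calls)))
  p <- allele_freq(x)
  cat(sprintf("  counted-allele frequency: %.3f-%.3f (%d monomorphic)\n",
              min(p, na.rm = TRUE), max(p, na.rm = TRUE),
              sum(p %in% c(0, 1))))
  invisible(x)
}

#' @export
dim.cgsa_genotypes <- function(x) dim(x$calls)

#' Counted-allele frequency per SNP
#'
#' Frequency of the counted allele at each SNP, estimated from non-missing
#' calls only (`sum(dosage) / (2 * n_nonmissing)`).
#'
#' @param g a [genotype_matrix()] object.
#' @return Named numeric vector of frequencies in `[0, 1]`; `NaN` for a SNP
#'   with no non-missing calls.
#' @export
allele_freq <- function(g) {
  stopifnot(inherits(g, "cgsa_genotypes"))
  colSums(g$calls, na.rm = TRUE) / (2 * colSums(!is.na(g$calls)))
}

#' Read PLINK 1.x text genotype files
#'
#' Parses a `.ped`/`.map` pair (whitespace-delimited PLINK text dialect,
#' biallelic SNPs) into a dosage matrix. Dosage counts the minor allele as
#' computed from the file itself; when both alleles have frequency 0.5 the
#' tie is broken by counting the lexicographically smaller allele symbol.
#' The PLINK missing genotype `0 0` maps to `NA`. A half-missing call
#' (one allele `0`) is also treated as missing. A SNP with a single observed
#' allele is monomorphic: its counted (minor) allele is the unobserved one,
#' every dosage is 0, and the SNP is kept but reported via a warning since
#' its frequency flags it for downstream exclusion.
#'
#' @param ped_path path to the `.ped` file (6 leading columns: family,
#'   individual, father, mother, sex, phenotype; then 2 allele columns per
#'   SNP).
#' @param map_path path to the `.map` file (4 columns: chromosome, SNP id,
#'   genetic distance, base-pair position). SNP order follows this file.
#' @return A [genotype_matrix()] object with positions taken from the map.
#' @export
read_plink_text <- function(ped_path, map_path) {
  map_lines <- readLines(map_path)
  map_lines <- map_lines[nzchar(trimws(map_lines))]
  map_fields <- strsplit(trimws(map_lines), "[ \t]+")
  if (any(lengths(map_fields) < 4L))
    stop("malformed .map line: expected 4 columns")
  map <- data.frame(
    chrom = vapply(map_fields, `[`, "", 1L),
    snp_id = vapply(map_fields, `[`, "", 2L),
    pos = as.integer(vapply(map_fields, `[`, "", 4L)),
    stringsAsFactors = FALSE)
  m <- nrow(map)

  ped_lines <- readLines(ped_path)
  ped_lines <- ped_lines[nzchar(trimws(ped_lines))]
  n <- length(ped_lines)
  expected <- 6L + 2L * m
  a1 <- a2 <- matrix(NA_character_, n, m)
  ids <- character(n)
  for (i in seq_len(n)) {
    f <- strsplit(trimws(ped_lines[i]), "[ \t]+")[[1]]
    if (length(f) != expected)
      stop(sprintf(".ped line %d has %d fields, expected %d",
                   i, length(f), expected))
    ids[i] <- f[2L]
    al <- f[-(1:6)]
    a1[i, ] <- al[seq(1L, by = 2L, length.out = m)]
    a2[i, ] <- al[seq(2L, by = 2L, length.out = m)]
  }
  a1[a1 == "0"] <- NA
  a2[a2 == "0"] <- NA
  # a call with either allele missing is fully missing
  miss <- is.na(a1) | is.na(a2)
  a1[miss] <- NA
  a2[miss] <- NA

  calls <- matrix(NA_integer_, n, m)
  counted <- character(m)
  for (k in seq_len(m)) {
    al <- c(a1[, k], a2[, k])
    al <- al[!is.na(al)]
    lev <- sort(unique(al))
    if (length(lev) > 2L)
      stop(sprintf("SNP %s has %d alleles; only biallelic SNPs supported",
                   map$snp_id[k], length(lev)))
    if (length(lev) == 0L) {       # all missing: counted allele undefined
      counted[k] <- NA_character_
      next
    }
    if (length(lev) == 1L) {
      # monomorphic: the counted (minor) allele is the unobserved one,
      # so every non-missing dosage is 0 (frequency 0 flags the SNP)
      counted[k] <- NA_character_
      calls[!is.na(a1[, k]), k] <- 0L
      next
    }
    cnt <- table(factor(al, levels = lev))
    # minor allele; tie (MAF 0.5) -> lexicographically smaller symbol
    counted[k] <- lev[order(cnt, lev)][1L]
    calls[, k] <- (a1[, k] == counted[k]) + (a2[, k] == counted[k])
  }
  g <- genotype_matrix(calls, ids, map$snp_id,
                       positions = data.frame(snp_id = map$snp_id,
                                              chrom = map$chrom,
                                              pos = map$pos))
  p <- allele_freq(g)
  mono <- g$snp_ids[!is.na(p) & (p == 0 | p == 1)]
  if (length(mono))
    warning("monomorphic SNP(s) kept with frequency 0 or 1: ",
            paste(mono, collapse = ", "))
  attr(g, "counted_allele") <- counted
  g
}

#' Write PLINK 1.x text genotype files
#'
#' Inverse of [read_plink_text()]: dosages are rendered with synthetic allele
#' symbols chosen so that re-reading the files recovers the same dosage
#' coding (the counted allele is written as the minor, or lexicographically
#' smaller on a tie). Missing calls are written as `0 0`.
#'
#' @param g a [genotype_matrix()] object.
#' @param ped_path,map_path output file paths.
#' @return Invisibly, the input `g`.
#' @export
write_plink_text <- function(g, ped_path, map_path) {
  stopifnot(inherits(g, "cgsa_genotypes"))
  m <- ncol(g$calls)
  pos <- g$positions
  if (is.null(pos))
    pos <- data.frame(snp_id = g$snp_ids, chrom = "1", pos = seq_len(m))
  writeLines(sprintf("%s\t%s\t0\t%d", pos$chrom, pos$snp_id, pos$pos),
             map_path)

  p <- allele_freq(g)
  # ensure the counted allele is recoverable as the minor ("A" < "B" on tie)
  sym_counted <- ifelse(!is.na(p) & p > 0.5, "B", "A")
  sym_other <- ifelse(sym_counted == "A", "B", "A")
  lines <- character(nrow(g$calls))
  for (i in seq_len(nrow(g$calls))) {
    d <- g$calls[i, ]
    al1 <- ifelse(is.na(d), "0", ifelse(d >= 1L, sym_counted, sym_other))
    al2 <- ifelse(is.na(d), "0", ifelse(d == 2L, sym_counted, sym_other))
    lines[i] <- paste(c(g$individual_ids[i], g$individual_ids[i],
                        "0", "0", "0", "-9", rbind(al1, al2)),
                      collapse = "\t")
  }
  writeLines(lines, ped_path)
  invisible(g)
}

#' Read or write a plain dosage-matrix TSV
#'
#' A simple alternative carrier to PLINK text: a TSV with individuals in
#' rows, an `id` first column, and one 0/1/2 dosage column per SNP (empty or
#' `NA` cells are missing).
#'
#' @param path file path.
#' @return A [genotype_matrix()] object (without map positions).
#' @export
read_genotype_tsv <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  ids <- as.character(tab[[1L]])
  mat <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(mat) <- "integer"
  genotype_matrix(mat, ids, colnames(mat))
}

#' @rdname read_genotype_tsv
#' @param g a [genotype_matrix()] object to write.
#' @export
write_genotype_tsv <- function(g, path) {
  stopifnot(inherits(g, "cgsa_genotypes"))
  tab <- data.frame(id = g$individual_ids, g$calls, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(g)
}

#' Read a phenotype and covariate table
#'
#' Tab-separated table with a header; the first column (or a column named
#' `id`) holds individual identifiers. Remaining columns are traits (numeric)
#' or covariates (non-numeric, read as categorical). Missing trait values are
#' kept as `NA` and reported, never dropped.
#'
#' @param path TSV file path.
#' @param covariates optional character vector naming columns to force to
#'   categorical even if numeric-looking (e.g. an integer-coded sire).
#' @return A `data.frame` of class `cgsa_phenotypes` with character `id`
#'   column, numeric trait columns and factor covariate columns.
#' @export
read_phenotypes <- function(path, covariates = NULL) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  idc <- if ("id" %in% names(tab)) "id" else names(tab)[1L]
  tab$id <- as.character(tab[[idc]])
  if (idc != "id") tab[[idc]] <- NULL
  tab <- tab[c("id", setdiff(names(tab), "id"))]
  if (anyDuplicated(tab$id)) stop("duplicate individual ids in ", path)
  for (nm in setdiff(names(tab), "id")) {
    if (nm %in% covariates || !is.numeric(tab[[nm]])) {
      tab[[nm]] <- factor(tab[[nm]])
      if (nlevels(tab[[nm]]) < 1L)
        stop("covariate '", nm, "' has no observed levels")
    }
  }
  nmiss <- vapply(tab[setdiff(names(tab), "id")],
                  function(x) sum(is.na(x)), 0L)
  if (any(nmiss > 0))
    message("missing values kept as NA: ",
            paste(sprintf("%s (%d)", names(nmiss)[nmiss > 0],
                          nmiss[nmiss > 0]), collapse = ", "))
  class(tab) <- c("cgsa_phenotypes", "data.frame")
  tab
}

#' Read gene annotation, QTL and gene-set membership tables
#'
#' All three inputs are TSV files with headers. Gene tables need columns
#' `gene_id`, `chrom`, `start`, `end`; QTL tables need `QTL_ID`,
#' `QTL_symbol`, `Trait_name`, `QTL_start`, `QTL_end` and optionally `chrom`
#' (filled with `default_chrom` when absent, for single-chromosome tables);
#' gene-set tables need `set` and `gene_id` (optionally `snp_id`).
#' Coordinates are 1-based inclusive throughout. Records violating
#' `start <= end`, non-positive coordinates, or duplicated `QTL_ID` are
#' rejected with an error naming the record.
#'
#' @param genes_path,qtl_path,geneset_path file paths; any may be `NULL` to
#'   skip that table.
#' @param default_chrom chromosome label assigned to QTL records when the
#'   table has no `chrom` column.
#' @return A list with elements `genes`, `qtl` and `geneset` (those
#'   requested; `NULL` otherwise). `genes` and `qtl` are `data.frame`s with
#'   normalised column names (`gene_id`/`qtl_id`, `chrom`, `start`, `end`,
#'   plus `qtl_symbol`, `trait_name`).
#' @export
read_tables <- function(genes_path = NULL, qtl_path = NULL,
                        geneset_path = NULL, default_chrom = "1") {
  out <- list(genes = NULL, qtl = NULL, geneset = NULL)
  if (!is.null(genes_path)) {
    g <- utils::read.delim(genes_path, stringsAsFactors = FALSE,
                           comment.char = "#")
    req <- c("gene_id", "chrom", "start", "end")
    if (!all(req %in% names(g)))
      stop("gene table needs columns: ", paste(req, collapse = ", "))
    g$gene_id <- as.character(g$gene_id)
    g$chrom <- as.character(g$chrom)
    g$start <- as.integer(g$start)
    g$end <- as.integer(g$end)
    bad <- which(g$start > g$end | g$start < 1L)
    if (length(bad))
      stop("invalid gene interval for: ",
           paste(g$gene_id[bad], collapse = ", "))
    out$genes <- g[req]
  }
  if (!is.null(qtl_path)) {
    q <- utils::read.delim(qtl_path, stringsAsFactors = FALSE,
                           comment.char = "#")
    req <- c("QTL_ID", "QTL_symbol", "Trait_name", "QTL_start", "QTL_end")
    if (!all(req %in% names(q)))
      stop("QTL table needs columns: ", paste(req, collapse = ", "))
    qq <- data.frame(
      qtl_id = as.character(q$QTL_ID),
      qtl_symbol = as.character(q$QTL_symbol),
      trait_name = as.character(q$Trait_name),
      chrom = if ("chrom" %in% names(q)) as.character(q$chrom)
              else default_chrom,
      start = as.integer(q$QTL_start),
      end = as.integer(q$QTL_end),
      stringsAsFactors = FALSE)
    if (anyDuplicated(qq$qtl_id))
      stop("duplicate QTL_ID: ",
           paste(unique(qq$qtl_id[duplicated(qq$qtl_id)]), collapse = ", "))
    bad <- which(qq$start > qq$end | qq$start < 1L)
    if (length(bad))
      stop("invalid QTL interval for QTL_ID: ",
           paste(qq$qtl_id[bad], collapse = ", "))
    out$qtl <- qq
  }
  if (!is.null(geneset_path)) {
    s <- utils::read.delim(geneset_path, stringsAsFactors = FALSE,
                           comment.char = "#")
    if (nrow(s) == 0L) {
      warning("empty gene-set file: ", geneset_path)
      out$geneset <- data.frame(set = character(), gene_id = character(),
                                stringsAsFactors = FALSE)
    } else {
      req <- c("set", "gene_id")
      if (!all(req %in% names(s)))
        stop("gene-set table needs columns: ", paste(req, collapse = ", "))
      s$set <- as.character(s$set)
      s$gene_id <- as.character(s$gene_id)
      s <- unique(s)
      out$geneset <- s
    }
  }
  out
}

#' Align genotype and phenotype tables on shared individuals
#'
#' Joins a genotype matrix and phenotype table on individual identifiers,
#' reordering both to a common order (the genotype order restricted to the
#' intersection). Individuals present in only one input are dropped and
#' counted, never silently discarded.
#'
#' @param g a [genotype_matrix()] object.
#' @param pheno a `data.frame` with character `id` column (e.g. from
#'   [read_phenotypes()]).
#' @return A list with `genotypes` (subset `cgsa_genotypes`), `pheno`
#'   (reordered `data.frame`), `n_dropped` (total dropped) and
#'   `dropped_ids` (list with `genotype_only`, `phenotype_only`).
#' @export
align_samples <- function(g, pheno) {
  stopifnot(inherits(g, "cgsa_genotypes"), "id" %in% names(pheno))
  common <- intersect(g$individual_ids, pheno$id)
  if (length(common) == 0L)
    stop("no overlapping individual identifiers between genotypes and phenotypes")
  keep <- g$individual_ids[g$individual_ids %in% common]
  g2 <- genotype_matrix(g$calls[keep, , drop = FALSE], keep, g$snp_ids,
                        positions = g$positions)
  ph2 <- pheno[match(keep, pheno$id), , drop = FALSE]
  rownames(ph2) <- NULL
  dropped <- list(genotype_only = setdiff(g$individual_ids, common),
                  phenotype_only = setdiff(pheno$id, common))
  list(genotypes = g2, pheno = ph2,
       n_dropped = length(dropped$genotype_only) +
         length(dropped$phenotype_only),
       dropped_ids = dropped)
}
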