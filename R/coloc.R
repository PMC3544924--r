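genes_to_granges <- function(genes, flank = 0L) {
  GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = pmax(1L, genes$start - flank),
                              end = genes$end + flank),
    gene_id = genes$gene_id)
}

#' Assign SNPs to genes with flanking windows
#'
#' A SNP is assigned to a gene when it lies on the same chromosome within
#' `[start - flank_bp, end + flank_bp]` (1-based inclusive; the lower bound
#' is floored at position 1). A SNP inside two overlapping windows is
#' assigned to both genes.
#'
#' @param snp_positions `data.frame` with columns `snp_id`, `chrom`, `pos`
#'   (e.g. the `positions` element of a [genotype_matrix()]).
#' @param genes gene annotation `data.frame` with columns `gene_id`,
#'   `chrom`, `start`, `end` (from [read_tables()]).
#' @param flank_bp flanking window in base pairs on each side (default
#'   50000, i.e. gene body plus 50 kb upstream and downstream).
#' @return List with `assignments` (`data.frame`: `snp_id`, `gene_id`,
#'   sorted) and `unassigned` (character vector of SNP ids matching no
#'   gene).
#' @export
assign_snps_to_genes <- function(snp_positions, genes, flank_bp = 50000L) {
  stopifnot(flank_bp >= 0)
  snp_positions <- as.data.frame(snp_positions)
  req <- c("snp_id", "chrom", "pos")
  if (!all(req %in% names(snp_positions)))
    stop("snp_positions needs columns: ", paste(req, collapse = ", "))
  gr_g <- genes_to_granges(genes, flank = as.integer(flank_bp))
  gr_s <- GenomicRanges::GRanges(
    seqnames = snp_positions$chrom,
    ranges = IRanges::IRanges(start = snp_positions$pos, width = 1L))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(gr_s, gr_g))
  asn <- data.frame(
    snp_id = snp_positions$snp_id[S4Vectors::queryHits(hits)],
    gene_id = genes$gene_id[S4Vectors::subjectHits(hits)],
    stringsAsFactors = FALSE)
  asn <- asn[order(asn$snp_id, asn$gene_id), , drop = FALSE]
  rownames(asn) <- NULL
  list(assignments = asn,
       unassigned = setdiff(snp_positions$snp_id, asn$snp_id))
}

#' Co-localize candidate genes with QTL confidence intervals
#'
#' Matches each gene's interval against every QTL interval on the same
#' chromosome. Under `mode = "overlap"` (default) a match is any nonempty
#' intersection of the 1-based inclusive intervals; under
#' `mode = "containment"` the gene interval must lie entirely within the QTL
#' confidence interval. Every match is additionally annotated with whether
#' the gene is fully contained in the QTL. QTL with confidence intervals
#' wider than `max_qtl_width` can be filtered out beforehand (off by
#' default), a guard against very wide intervals swamping the counts.
#'
#' @param genes gene `data.frame` (`gene_id`, `chrom`, `start`, `end`).
#' @param qtl QTL `data.frame` (`qtl_id`, `qtl_symbol`, `trait_name`,
#'   `chrom`, `start`, `end`), e.g. from [read_tables()].
#' @param mode `"overlap"` or `"containment"`.
#' @param max_qtl_width drop QTL whose interval width (end - start + 1)
#'   exceeds this (default `Inf`, no filter).
#' @return An object of class `cgsa_overlap_report`: list with `matches`
#'   (`data.frame`: `gene_id`, `qtl_id`, `qtl_symbol`, `trait_name`,
#'   `contained`, ordered by gene then QTL id), `counts` (named integer
#'   vector per gene, zero-match genes included), `mode`, and `notes`
#'   (genes whose chromosome never occurs in the QTL table).
#' @export
colocalize <- function(genes, qtl, mode = c("overlap", "containment"),
                       max_qtl_width = Inf) {
  mode <- match.arg(mode)
  if (is.finite(max_qtl_width))
    qtl <- qtl[(qtl$end - qtl$start + 1) <= max_qtl_width, , drop = FALSE]
  gr_g <- genes_to_granges(genes)
  gr_q <- GenomicRanges::GRanges(
    seqnames = qtl$chrom,
    ranges = IRanges::IRanges(start = qtl$start, end = qtl$end))
  type <- if (mode == "containment") "within" else "any"
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(gr_g, gr_q, type = type))
  gi <- S4Vectors::queryHits(hits)
  qi <- S4Vectors::subjectHits(hits)
  contained <- genes$start[gi] >= qtl$start[qi] &
    genes$end[gi] <= qtl$end[qi] &
    genes$chrom[gi] == qtl$chrom[qi]
  matches <- data.frame(
    gene_id = genes$gene_id[gi],
    qtl_id = qtl$qtl_id[qi],
    qtl_symbol = qtl$qtl_symbol[qi],
    trait_name = qtl$trait_name[qi],
    contained = contained,
    stringsAsFactors = FALSE)
  # deterministic order: gene, then QTL id (numeric when possible)
  qnum <- suppressWarnings(as.numeric(matches$qtl_id))
  ord <- if (anyNA(qnum)) order(matches$gene_id, matches$qtl_id)
         else order(matches$gene_id, qnum)
  matches <- matches[ord, , drop = FALSE]
  rownames(matches) <- NULL
  counts <- table(factor(matches$gene_id, levels = sort(genes$gene_id)))
  counts <- stats::setNames(as.integer(counts), names(counts))
  notes <- genes$gene_id[!(genes$chrom %in% qtl$chrom)]
  structure(list(matches = matches, counts = counts, mode = mode,
                 notes = if (length(notes))
                   paste0("no QTL on the chromosome of: ",
                          paste(notes, collapse = ", "))
                 else character(0)),
            class = "cgsa_overlap_report")
}

#' @export
print.cgsa_overlap_report <- function(x, ...) {
  cat(sprintf("cgsa_overlap_report (%s): %d gene(s), %d match(es)\n",
              x$mode, length(x$counts), nrow(x$matches)))
  print(sort(x$counts, decreasing = TRUE))
  if (length(x$notes)) cat("note:", x$notes, "\n")
  invisible(x)
}

#' Rank genes by QTL co-localization multiplicity
#'
#' Genes overlapping many QTL of interest are the strongest positional
#' candidates; this orders a report by descending overlap count, breaking
#' ties lexicographically by gene id.
#'
#' @param report a `cgsa_overlap_report` from [colocalize()], or a named
#'   integer vector of per-gene counts.
#' @return A `data.frame` with columns `gene_id` and `n_qtl`, ordered.
#' @export
rank_by_multiplicity <- function(report) {
  counts <- if (inherits(report, "cgsa_overlap_report")) report$counts
            else report
  if (length(counts) == 0L) stop("empty co-localization report")
  ord <- order(-counts, names(counts))
  data.frame(gene_id = names(counts)[ord],
             n_qtl = as.integer(counts[ord]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Export gene (or QTL) intervals as BED
#'
#' Writes 1-based inclusive intervals as 0-based half-open BED records
#' (`start - 1`, `end`), optionally widened by a flank.
#'
#' @param intervals `data.frame` with `chrom`, `start`, `end` and an id
#'   column (`gene_id` or `qtl_id`).
#' @param path output path.
#' @param flank_bp flank added on both sides before conversion.
#' @export
write_bed <- function(intervals, path, flank_bp = 0L) {
  idc <- intersect(c("gene_id", "qtl_id"), names(intervals))[1L]
  if (is.na(idc)) stop("intervals need a gene_id or qtl_id column")
  bed <- data.frame(chrom = intervals$chrom,
                    start = pmax(0L, intervals$start - 1L - flank_bp),
                    end = intervals$end + flank_bp,
                    name = intervals[[idc]])
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
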