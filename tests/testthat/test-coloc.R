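fixture_tables <- function() {
  read_tables(
    genes_path = system.file("extdata", "igf1_foxo_genes.tsv",
                             package = "cgsa"),
    qtl_path = system.file("extdata", "foxo3_qtl.tsv", package = "cgsa"))
}

test_that("SNP-to-gene assignment uses inclusive 50 kb boundaries", {
  genes <- data.frame(gene_id = "G1", chrom = "1",
                      start = 1000000L, end = 1500000L,
                      stringsAsFactors = FALSE)
  snps <- data.frame(
    snp_id = c("at_edge", "past_edge", "inside", "wrong_chrom"),
    chrom = c("1", "1", "1", "2"),
    pos = c(950000L, 949999L, 1200000L, 1200000L),
    stringsAsFactors = FALSE)
  res <- assign_snps_to_genes(snps, genes, flank_bp = 50000L)
  expect_setequal(res$assignments$snp_id, c("at_edge", "inside"))
  expect_setequal(res$unassigned, c("past_edge", "wrong_chrom"))
})

test_that("a SNP inside two overlapping gene windows is assigned to both", {
  genes <- data.frame(gene_id = c("G1", "G2"), chrom = "1",
                      start = c(100L, 150L), end = c(200L, 260L),
                      stringsAsFactors = FALSE)
  snps <- data.frame(snp_id = "s", chrom = "1", pos = 180L,
                     stringsAsFactors = FALSE)
  res <- assign_snps_to_genes(snps, genes, flank_bp = 0L)
  expect_identical(res$assignments$gene_id, c("G1", "G2"))
})

test_that("widening the flank never loses assignments", {
  set.seed(7)
  genes <- data.frame(gene_id = sprintf("G%02d", 1:8), chrom = "1",
                      start = sort(sample.int(1e6, 8)),
                      stringsAsFactors = FALSE)
  genes$end <- genes$start + sample.int(5e4, 8)
  snps <- data.frame(snp_id = sprintf("s%02d", 1:40), chrom = "1",
                     pos = sample.int(1.2e6, 40), stringsAsFactors = FALSE)
  counts <- vapply(c(0L, 10000L, 50000L, 200000L), function(fl)
    nrow(assign_snps_to_genes(snps, genes, flank_bp = fl)$assignments), 0L)
  expect_true(all(diff(counts) >= 0))
})

test_that("FOXO3 overlaps and is contained in QTL 5928", {
  tabs <- fixture_tables()
  foxo3 <- tabs$genes[tabs$genes$gene_id == "FOXO3", ]
  rep_o <- colocalize(foxo3, tabs$qtl[tabs$qtl$qtl_id == "5928", ])
  expect_identical(unname(rep_o$counts["FOXO3"]), 1L)
  expect_true(rep_o$matches$contained)
  rep_c <- colocalize(foxo3, tabs$qtl[tabs$qtl$qtl_id == "5928", ],
                      mode = "containment")
  expect_identical(unname(rep_c$counts["FOXO3"]), 1L)
})

test_that("FOXO3 co-localizes with all 48 curated QTL in either mode", {
  tabs <- fixture_tables()
  foxo3 <- tabs$genes[tabs$genes$gene_id == "FOXO3", ]
  for (mode in c("overlap", "containment")) {
    rep <- colocalize(foxo3, tabs$qtl, mode = mode)
    expect_identical(unname(rep$counts["FOXO3"]), 48L, info = mode)
  }
})

test_that("co-localization matches a brute-force interval oracle", {
  set.seed(17)
  genes <- data.frame(gene_id = sprintf("G%02d", 1:10),
                      chrom = sample(c("1", "2"), 10, TRUE),
                      start = sample.int(1000, 10), stringsAsFactors = FALSE)
  genes$end <- genes$start + sample.int(300, 10)
  qtl <- data.frame(qtl_id = as.character(1:25),
                    qtl_symbol = "Q", trait_name = "t",
                    chrom = sample(c("1", "2"), 25, TRUE),
                    start = sample.int(1000, 25), stringsAsFactors = FALSE)
  qtl$end <- qtl$start + sample.int(400, 25)
  rep <- colocalize(genes, qtl)
  brute <- 0L
  for (i in seq_len(nrow(genes))) for (j in seq_len(nrow(qtl)))
    if (genes$chrom[i] == qtl$chrom[j] &&
        genes$start[i] <= qtl$end[j] && genes$end[i] >= qtl$start[j])
      brute <- brute + 1L
  expect_identical(nrow(rep$matches), brute)
  # containment implies overlap for every reported pair
  rep_c <- colocalize(genes, qtl, mode = "containment")
  expect_true(all(rep_c$matches$contained))
  key <- function(m) paste(m$gene_id, m$qtl_id)
  expect_true(all(key(rep_c$matches) %in% key(rep$matches)))
  # symmetry: swapping roles transposes the overlap match set
  qtl_as_genes <- data.frame(gene_id = qtl$qtl_id, chrom = qtl$chrom,
                             start = qtl$start, end = qtl$end,
                             stringsAsFactors = FALSE)
  genes_as_qtl <- data.frame(qtl_id = genes$gene_id, qtl_symbol = "G",
                             trait_name = "t", chrom = genes$chrom,
                             start = genes$start, end = genes$end,
                             stringsAsFactors = FALSE)
  rep_t <- colocalize(qtl_as_genes, genes_as_qtl)
  expect_setequal(paste(rep$matches$gene_id, rep$matches$qtl_id),
                  paste(rep_t$matches$qtl_id, rep_t$matches$gene_id))
})

test_that("genes on chromosomes absent from the QTL table get a note", {
  genes <- data.frame(gene_id = c("G1", "G2"), chrom = c("1", "X"),
                      start = c(10L, 10L), end = c(20L, 20L),
                      stringsAsFactors = FALSE)
  qtl <- data.frame(qtl_id = "1", qtl_symbol = "Q", trait_name = "t",
                    chrom = "1", start = 1L, end = 100L,
                    stringsAsFactors = FALSE)
  rep <- colocalize(genes, qtl)
  expect_identical(unname(rep$counts["G2"]), 0L)
  expect_match(rep$notes, "G2")
})

test_that("the QTL width filter drops oversized confidence intervals", {
  tabs <- fixture_tables()
  foxo3 <- tabs$genes[tabs$genes$gene_id == "FOXO3", ]
  widths <- tabs$qtl$end - tabs$qtl$start + 1
  lim <- sort(widths)[10]
  rep <- colocalize(foxo3, tabs$qtl, max_qtl_width = lim)
  expect_identical(unname(rep$counts["FOXO3"]), sum(widths <= lim))
  expect_lt(sum(widths <= lim), 48L)
})

test_that("multiplicity ranking orders by count then gene id", {
  counts <- c(FOXO3 = 48L, FOXO6 = 32L, IGFBP6 = 27L, FOXO1 = 22L,
              PDK3 = 4L)
  rk <- rank_by_multiplicity(counts)
  expect_identical(rk$gene_id, c("FOXO3", "FOXO6", "IGFBP6", "FOXO1",
                                 "PDK3"))
  tie <- c(B = 3L, A = 3L, C = 3L)
  expect_identical(rank_by_multiplicity(tie)$gene_id, c("A", "B", "C"))
  expect_identical(rank_by_multiplicity(c(ONLY = 1L))$gene_id, "ONLY")
  expect_error(rank_by_multiplicity(integer(0)), "empty")
})

test_that("match tables are deterministically ordered by gene then QTL id", {
  tabs <- fixture_tables()
  rep <- colocalize(tabs$genes, tabs$qtl)
  m <- rep$matches[rep$matches$gene_id == "FOXO3", ]
  expect_identical(m$qtl_id, m$qtl_id[order(as.numeric(m$qtl_id))])
})

test_that("BED export converts to 0-based half-open coordinates", {
  genes <- data.frame(gene_id = "G1", chrom = "1", start = 100L, end = 200L,
                      stringsAsFactors = FALSE)
  path <- tempfile(fileext = ".bed")
  write_bed(genes, path)
  bed <- read.table(path, sep = "\t")
  expect_identical(bed$V2, 99L)
  expect_identical(bed$V3, 200L)
})
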