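# Domain types, file readers/writers, scaffold assignment.

test_that("site-count TSV reading maps fields and validates", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("scaffold\tpos\tsample\tA\tC\tG\tT",
               "scaf1\t100\tM1\t5\t5\t0\t0",
               "scaf1\t101\tM1\t8\t0\t0\t2"), tf)
  sc <- readSiteCounts(tf)
  expect_equal(nrow(sc), 2L)
  expect_equal(sc$coverage, c(10L, 10L))
  expect_equal(unlist(sc[1, c("A", "C", "G", "T")], use.names = FALSE),
    c(5L, 5L, 0L, 0L))

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("scaffold\tpos\tsample\tA\tC\tG\tT",
               "scaf1\t100\tM1\t-1\t5\t0\t0"), bad)
  expect_error(readSiteCounts(bad), "negative")
})

test_that("empty site-count file yields an empty collection with a warning", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines("scaffold\tpos\tsample\tA\tC\tG\tT", tf)
  expect_warning(sc <- readSiteCounts(tf), "no sites")
  expect_equal(nrow(sc), 0L)
})

test_that("mpileup symbol grammar is decoded against the reference base", {
  tf <- withr::local_tempfile(fileext = ".pileup")
  writeLines(c(
    "scaf1\t100\tA\t6\t.....,\tIIIIII",          # 6 ref matches -> A=6
    "scaf1\t101\tC\t5\t..TtN\tIIIII",            # C=2, T=2, N skipped
    "scaf1\t102\tG\t4\t.$.,+2AC,\tIIII",         # end mark + insertion skipped
    "scaf1\t103\tT\t4\t^F..-1a,*\tIIII",         # start+mapq, deletion, * skipped
    "scaf1\t104\tN\t2\t.,\tII"                   # unknown ref -> no counts
  ), tf)
  sc <- readSiteCounts(tf, format = "mpileup", sample_id = "M1")
  expect_equal(sc$A, c(6L, 0L, 0L, 0L, 0L))
  expect_equal(sc$C, c(0L, 2L, 0L, 0L, 0L))
  expect_equal(sc$G, c(0L, 0L, 4L, 0L, 0L))
  expect_equal(sc$T, c(0L, 2L, 0L, 3L, 0L))
  expect_equal(sc$coverage, c(6L, 4L, 4L, 3L, 0L))
})

test_that("TSV write/read round-trips site counts", {
  spec <- tinySpec(seed = 4)
  sim <- simulateSiteCounts(spec, "lab")
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeSiteCounts(sim$sites, tf)
  back <- readSiteCounts(tf)
  orig <- data.table::as.data.table(sim$sites)
  data.table::setkey(orig, scaffold_id, pos, sample_id)
  expect_equal(back$A, orig$A)
  expect_equal(back$coverage, orig$coverage)
})

test_that("scaffold assignment follows the 70% gene-majority rule", {
  mkHits <- function(n12, nOther, scaf = "scaf1") data.frame(
    gene_id = paste0(scaf, "_g", seq_len(n12 + nOther)), scaffold_id = scaf,
    ref_chromosome = rep(c("chr12", "chr3"), c(n12, nOther)),
    ref_start = 1e5 * seq_len(n12 + nOther))
  lay <- assignScaffolds(mkHits(7, 3))           # 7/10 assigned
  expect_equal(scaffoldTable(lay)$chromosome, "chr12")
  expect_error(assignScaffolds(mkHits(6, 4)), "majority")  # 6/10 discarded
  lay1 <- assignScaffolds(mkHits(1, 0))          # 1/1 = 100%
  expect_equal(scaffoldTable(lay1)$chromosome, "chr12")

  expect_error(assignScaffolds(mkHits(7, 3), threshold = 0.5), "threshold")
  expect_error(assignScaffolds(mkHits(7, 3), threshold = 1.2), "threshold")
  expect_error(assignScaffolds(data.frame()), "empty")
})

test_that("scaffold assignment is order-independent and orders by median gene start", {
  set.seed(42)
  hits <- do.call(rbind, lapply(1:6, function(i) data.frame(
    gene_id = sprintf("s%d_g%d", i, 1:5), scaffold_id = sprintf("scaf%d", i),
    ref_chromosome = "chr2", ref_start = sample.int(5e6, 5) + i * 3e6)))
  lay1 <- assignScaffolds(hits)
  lay2 <- assignScaffolds(hits[sample.int(nrow(hits)), ])
  expect_identical(scaffoldTable(lay1), scaffoldTable(lay2))
  # ordering along the chromosome follows the median reference start
  med <- vapply(split(hits$ref_start, hits$scaffold_id), median, numeric(1))
  expect_identical(scaffoldTable(lay1)$scaffold_id,
    names(sort(med)))
})

test_that("genes on discarded scaffolds vanish from located gene tables", {
  hits <- rbind(
    data.frame(gene_id = paste0("a", 1:4), scaffold_id = "keep",
      ref_chromosome = "chr1", ref_start = 1:4 * 1e5),
    data.frame(gene_id = paste0("b", 1:4), scaffold_id = "drop",
      ref_chromosome = rep(c("chr1", "chr2"), each = 2),
      ref_start = 1:4 * 1e5))
  lay <- assignScaffolds(hits)
  expect_identical(attr(lay, "discarded"), "drop")
  genes <- data.frame(gene_id = c(paste0("a", 1:4), paste0("b", 1:4)),
    scaffold_id = rep(c("keep", "drop"), each = 4),
    start = 1, end = 10, strand = ".", exonicLength = 10)
  located <- suppressMessages(locateGenes(genes, lay))
  expect_identical(located$gene_id, paste0("a", 1:4))
})

test_that("track writing uses 0-based half-open output and round-trips values", {
  tr <- makeTrack(values = c(0.123456789012, -1), band = c(-0.5, 0.5),
    positions = c(1, 2, 3), window = 2L)
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeTrack(tr, tf)
  back <- readTrack(tf)
  expect_equal(back$start[1], 0)   # 1-based site 1 -> BED interval (0, 1]
  expect_equal(back$end[1], 2)
  expect_equal(back$value, trackValues(tr), tolerance = 1e-10)
  expect_equal(back$significant, c(FALSE, TRUE))

  empty <- new("WindowTrack", chromosome = "chr1", unitPos = numeric(),
    window = 1L, values = numeric(), ciLow = 0, ciHigh = 0,
    significant = logical())
  tf2 <- withr::local_tempfile(fileext = ".tsv")
  writeTrack(empty, tf2)
  expect_equal(nrow(readTrack(tf2)), 0L)   # header-only file
})

test_that("GenomeLayout validates and round-trips through TSV", {
  expect_error(GenomeLayout(
    data.frame(id = "chr1", length = 100, isSex = FALSE),
    data.frame(scaffold_id = c("a", "b"), chromosome = "chr1",
      chromStart = c(1, 40), chromEnd = c(50, 90))), "overlap")
  expect_error(GenomeLayout(
    data.frame(id = c("chr1", "chr2"), length = 100, isSex = TRUE),
    data.frame(scaffold_id = "a", chromosome = "chr1",
      chromStart = 1, chromEnd = 50)), "at most one")
  spec <- tinySpec()
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeGenomeLayout(spec@layout, tf)
  back <- readGenomeLayout(tf)
  expect_equal(scaffoldTable(back), scaffoldTable(spec@layout))
  expect_equal(sexChromosome(back), "chrX")
})

test_that("sample sheets and gene tables validate their columns", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tsex\tpopulation\tassay",
               "M1\tmale\tlab\tdna", "F1\tfemale\tlab\tdna"), tf)
  expect_equal(readSampleSheet(tf)$sex, c("male", "female"))
  writeLines(c("sample_id\tsex\tpopulation\tassay",
               "M1\tmale\tlab\tdna", "M1\tmale\tlab\tdna"), tf)
  expect_error(readSampleSheet(tf), "duplicate")

  gf <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chrom\tstart\tend\tname\tscore\tstrand\texonic_length",
               "scaf1\t0\t100\tg1\t0\t+\t100"), gf)
  g <- readGeneTable(gf)
  expect_equal(g$start, 1L)   # BED 0-based start -> 1-based internal
  expect_equal(g$end, 100L)
})
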