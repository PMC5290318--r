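# Coverage, SNP-density and expression statistics and their sex contrasts.

test_that("scaffold coverage averages only over sequenced sites", {
  mk <- function(cov) data.frame(scaffold_id = "s1", pos = seq_along(cov),
    sample_id = "M1", A = cov, C = 0L, G = 0L, T = 0L)
  expect_equal(scaffoldCoverage(mk(c(10, 20, 30)))$coverage, 20)
  expect_equal(scaffoldCoverage(mk(7))$coverage, 7)
  # zero-read sites drop out of the denominator
  expect_equal(scaffoldCoverage(mk(c(10, 0, 20)))$coverage, 15)
  expect_message(res <- scaffoldCoverage(mk(c(0, 0))), "no sequenced site")
  expect_equal(nrow(res), 0L)
})

test_that("log2 M:F contrast honours the pseudocount and is antisymmetric", {
  expect_equal(mfLog2Ratio(3, 1), 1)          # log2(4) - log2(2)
  expect_equal(mfLog2Ratio(5, 5), 0)
  expect_equal(mfLog2Ratio(0, 0), 0)          # pseudocount floor
  expect_error(mfLog2Ratio(-1, 2), "non-negative")
  set.seed(1)
  m <- rexp(200); f <- rexp(200)
  expect_equal(mfLog2Ratio(m, f), -mfLog2Ratio(f, m))
  expect_equal(mfLog2Ratio(m, f, pseudocount = 0.5),
    log2(m + 0.5) - log2(f + 0.5))
})

test_that("SNP calling excludes low-coverage sites and thresholds the minor allele", {
  s <- data.frame(scaffold_id = "s", pos = 1:3, sample_id = "M1",
    A = c(5L, 8L, 6L), C = c(5L, 2L, 3L), G = 0L, T = 0L)
  fl <- callSnpSites(s)
  expect_equal(fl$retained, c(TRUE, TRUE, FALSE))   # coverage 9 excluded
  expect_equal(fl$snp, c(TRUE, FALSE, FALSE))       # minor 5 >= 3; 2 < 3
  expect_error(callSnpSites(s, minCov = 0), "minCov")
  expect_error(callSnpSites(s, minorFrac = 0.6), "minorFrac")
  expect_error(callSnpSites(s, minorFrac = 0), "minorFrac")
})

test_that("SNP calls are monotone in the minor-allele count at fixed coverage", {
  cov <- 20L
  flags <- vapply(0:10, function(minor) {
    s <- data.frame(scaffold_id = "s", pos = 1L, sample_id = "M1",
      A = cov - minor, C = minor, G = 0L, T = 0L)
    callSnpSites(s)$snp
  }, logical(1))
  expect_true(all(diff(as.integer(flags)) >= 0))
  # the minor allele can sit in any base column
  s <- data.frame(scaffold_id = "s", pos = 1L, sample_id = "M1",
    A = 0L, C = 0L, G = 7L, T = 3L)
  expect_true(callSnpSites(s)$snp)
})

test_that("gene SNP density divides SNPs by filtered sites and drops empty genes", {
  sites <- data.frame(scaffold_id = "s", pos = 1:300, sample_id = "M1",
    A = 20L, C = 0L, G = 0L, T = 0L, gene_id = rep(c("g1", "g2"), c(200, 100)))
  sites$C[c(1, 2)] <- 10L          # two SNPs in g1
  sites$A[201:300] <- 5L           # g2 entirely below min coverage
  fl <- callSnpSites(sites)
  expect_message(gd <- geneSnpDensity(fl), "zero filtered sites")
  expect_equal(gd$gene_id, "g1")
  expect_equal(gd$density, 2 / 200)
  expect_equal(mfLog2Ratio(0, 0), 0)  # zero density logs to 0 after pseudocount
})

test_that("X-median normalization zeroes the X and shifts autosomes", {
  v <- c(1, 2, 3, 5)
  isX <- c(TRUE, TRUE, TRUE, FALSE)
  norm <- normalizeByXMedian(v, isX)
  expect_equal(norm, c(-1, 0, 1, 3))     # X median 2 subtracted
  expect_equal(median(norm[isX]), 0)
  expect_error(normalizeByXMedian(v, rep(FALSE, 4)), "no X-linked")
})

test_that("reference-relative contrasts act on the shared gene set", {
  pop <- c(g1 = 1, g2 = 2, g3 = 3)
  ref <- c(g2 = 0.5, g3 = 3, g4 = 9)
  expect_message(out <- relativeToReference(pop, ref), "dropped")
  expect_equal(out, c(g2 = 1.5, g3 = 0))
  expect_equal(unname(relativeToReference(pop, pop)), c(0, 0, 0))
  expect_error(relativeToReference(c(a = 1), c(b = 2)), "no shared genes")
})

test_that("RPKM follows count / kb / million-reads and validates inputs", {
  expect_equal(rpkm(matrix(10), lengths = 1000, librarySizes = 1e6)[1], 10)
  expect_equal(rpkm(matrix(0), lengths = 1000, librarySizes = 1e6)[1], 0)
  expect_equal(rpkm(matrix(20), lengths = 500, librarySizes = 2e6)[1], 20)
  expect_error(rpkm(matrix(1), lengths = 100, librarySizes = 0), "library")
})

test_that("expression filter keeps genes reaching 2 RPKM in half of either sex", {
  samples <- data.frame(sample_id = c(paste0("M", 1:4), paste0("F", 1:4)),
    sex = rep(c("male", "female"), each = 4))
  mat <- rbind(
    keepM = c(2, 2, 0, 0, 0, 0, 0, 0),     # exactly 2 of 4 males
    dropA = rep(1.9, 8),                   # under threshold everywhere
    keepF = c(0, 0, 0, 0, 2, 2, 0, 0))     # either-sex clause
  colnames(mat) <- samples$sample_id
  expect_setequal(expressionFilter(mat, samples), c("keepM", "keepF"))
  expect_error(
    expressionFilter(mat[, 1:4], samples[1:4, ]), "both sexes")
})

test_that("expression summary averages RPKM per sex before the contrast", {
  samples <- data.frame(sample_id = c("M1", "M2", "F1", "F2"),
    sex = c("male", "male", "female", "female"))
  mat <- matrix(c(3, 3, 1, 1), 1, dimnames = list("g1", samples$sample_id))
  summ <- expressionSummary(mat, samples)
  expect_equal(summ$maleRpkm, 3)
  expect_equal(summ$log2MF, 1)
})
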