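# Ortholog filters, sum-then-divide aggregation, permutation and bootstrap.

mkRows <- function(n, cat, dn, ds, N = 450, S = 150, seed = 1) {
  set.seed(seed)
  data.frame(gene_id = sprintf("%s_%d", cat, seq_len(n)), category = cat,
    DN = rpois(n, dn * N), DS = rpois(n, ds * S), N = N, S = S,
    branch_dS = ds, aln_len = N + S)
}

test_that("ortholog filters use strict length and saturation bounds", {
  rows <- data.frame(gene_id = c("a", "b", "c", "d"), category = "autosome",
    DN = 1, DS = 1, N = 100, S = 50,
    branch_dS = c(2.5, 0.1, 2.0, 0.1), aln_len = c(400, 250, 300, 400))
  kept <- suppressMessages(filterOrthologs(rows))
  expect_setequal(kept$gene_id, c("c", "d"))  # dS 2.0 and len 300 retained
})

test_that("aggregation is sum-then-divide and duplication-invariant", {
  rows <- data.frame(category = "autosome", DN = c(2, 4), DS = c(1, 3),
    N = c(100, 300), S = c(50, 150))
  agg <- aggregateDivergence(rows)
  expect_equal(agg$dN, 6 / 400)
  expect_equal(agg$dS, 4 / 200)
  expect_equal(agg$omega, (6 / 400) / (4 / 200))
  expect_equal(aggregateDivergence(rbind(rows, rows))$omega, agg$omega)
  one <- aggregateDivergence(rows[1, , drop = FALSE])
  expect_equal(one$omega, (2 / 100) / (1 / 50))
  expect_error(aggregateDivergence(rows, category = "X_all"), "no rows")
  zero <- data.frame(category = "a", DN = 1, DS = 0, N = 10, S = 10)
  expect_warning(res <- aggregateDivergence(zero), "undefined")
  expect_true(is.na(res$omega))
})

test_that("aggregation matches an independently parsed sum oracle", {
  set.seed(7)
  rows <- rbind(mkRows(50, "autosome", 0.01, 0.1, seed = 7),
                mkRows(50, "X_all", 0.02, 0.1, seed = 8))
  tf <- withr::local_tempfile(fileext = ".tsv")
  data.table::fwrite(rows, tf, sep = "\t")
  reread <- read.delim(tf)   # independent parse
  for (cat in c("autosome", "X_all")) {
    d <- reread[reread$category == cat, ]
    expect_equal(aggregateDivergence(rows, cat)$dN, sum(d$DN) / sum(d$N))
    expect_equal(aggregateDivergence(rows, cat)$omega,
      (sum(d$DN) / sum(d$N)) / (sum(d$DS) / sum(d$S)))
  }
})

test_that("ortholog reader reconstructs counts from rates when needed", {
  rows <- mkRows(10, "autosome", 0.01, 0.1, seed = 2)
  tf <- withr::local_tempfile(fileext = ".tsv")
  rates <- rows
  rates$dN <- rates$DN / rates$N
  rates$dS <- rates$DS / rates$S
  rates$DN <- NULL; rates$DS <- NULL
  data.table::fwrite(rates, tf, sep = "\t")
  back <- readOrthologTable(tf)
  expect_equal(back$DN, rows$DN)
  expect_equal(back$DS, rows$DS)
})

test_that("permutation P converges to the exact label-permutation tail", {
  rows <- rbind(mkRows(3, "X_all", 0.05, 0.1, seed = 3),
                mkRows(3, "autosome", 0.01, 0.1, seed = 4))
  exact <- permEnumOracle(rows, "X_all", "autosome", "omega")
  pt <- categoryPermutationTest(rows, "X_all", "autosome", "omega",
    reps = 4000, tail = "one_tailed_a_greater", seed = 5)
  expect_equal(pt$p, exact, tolerance = 0.035)
  pt2 <- categoryPermutationTest(rows, "X_all", "autosome", "omega",
    reps = 4000, tail = "one_tailed_a_greater", seed = 5)
  expect_identical(pt$p, pt2$p)   # seed-determinism
  expect_error(categoryPermutationTest(rows, "X_all", "autosome", "omega",
    reps = 0), "reps")
})

test_that("a doubled nonsynonymous rate is detected by the one-tailed omega test", {
  rows <- rbind(mkRows(500, "X_all", 0.03, 0.1, seed = 6),
                mkRows(500, "autosome", 0.015, 0.1, seed = 7))
  pt <- categoryPermutationTest(rows, "X_all", "autosome", "omega",
    reps = 499, tail = "one_tailed_a_greater", seed = 8)
  expect_lt(pt$p, 0.05)
})

test_that("bootstrap CI is degenerate for one row, covers the estimate, shrinks with n", {
  one <- mkRows(1, "autosome", 0.02, 0.1, seed = 9)
  ci <- bootstrapCIDivergence(one, "autosome", reps = 100, seed = 1)
  expect_equal(ci$ci_low, ci$estimate)
  expect_equal(ci$ci_high, ci$estimate)
  rows <- mkRows(400, "autosome", 0.02, 0.1, seed = 10)
  ci400 <- bootstrapCIDivergence(rows, "autosome", reps = 500, seed = 2)
  expect_true(all(ci400$ci_low <= ci400$estimate + 1e-12 &
                  ci400$estimate <= ci400$ci_high + 1e-12))
  ci100 <- bootstrapCIDivergence(rows[1:100, ], "autosome", reps = 500, seed = 3)
  wide <- ci100$ci_high - ci100$ci_low
  narrow <- ci400$ci_high - ci400$ci_low
  # quadrupling n should halve the width, within Monte-Carlo slack
  expect_true(all(wide / narrow > 1.4 & wide / narrow < 2.9))
})
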