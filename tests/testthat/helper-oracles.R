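# Independent oracles and shared fixture builders.

# Brute-force sliding-window means straight from the definition
# (sum over the window divided by the window size).
bruteWindowMeans <- function(x, w) {
  vapply(seq_len(length(x) - w + 1L),
    function(i) sum(x[i:(i + w - 1L)]) / w, numeric(1))
}

# Exact Wilcoxon rank-sum P by full enumeration of which pooled ranks land
# in sample x. Tie-free inputs only.
wilcoxEnumOracle <- function(x, y, alternative = "greater") {
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  uObs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  sets <- utils::combn(n + m, n)
  uAll <- apply(sets, 2L, function(idx) sum(r[idx]) - n * (n + 1) / 2)
  pGe <- mean(uAll >= uObs)
  pLe <- mean(uAll <= uObs)
  switch(alternative,
    greater = pGe, less = pLe,
    two_sided = min(1, 2 * min(pGe, pLe)))
}

# Exact label-permutation tail for the two-category divergence contrast
# (all choose(nA+nB, nA) splits enumerated).
permEnumOracle <- function(rows, catA, catB, statistic = "omega") {
  a <- rows[rows$category == catA, ]; b <- rows[rows$category == catB, ]
  pool <- rbind(a, b)
  stat <- function(d) switch(statistic,
    dN = sum(d$DN) / sum(d$N), dS = sum(d$DS) / sum(d$S),
    omega = (sum(d$DN) / sum(d$N)) / (sum(d$DS) / sum(d$S)))
  obs <- stat(a) - stat(b)
  sets <- utils::combn(nrow(pool), nrow(a))
  deltas <- apply(sets, 2L, function(idx)
    stat(pool[idx, ]) - stat(pool[-idx, ]))
  mean(deltas >= obs)
}

# Small genome used by most integration-style tests: 3 x 8 Mb autosomes,
# 8 Mb X with an old stratum at 5-6.5 Mb and a young stratum at 2.5-5 Mb.
smallSpec <- function(seed = 1, ...) {
  args <- list(seed = seed, nAutosomes = 3, autosomeLength = 8e6,
    sexLength = 8e6, scaffoldLength = 20e3, sitesPerGene = 40,
    strata = data.frame(name = c("stratum1", "stratum2"),
      start = c(5e6, 2.5e6), end = c(6.5e6, 5e6),
      yLoss = c(0.5, 0), xyDivergence = c(0.02, 0.02)),
    upExtent = 2.5e6, downExtent = 1.5e6)
  over <- list(...)
  args[names(over)] <- over
  do.call(simSpec, args)
}

smallNullSpec <- function(seed = 1, ...) {
  spec <- smallSpec(seed = seed, ...)
  if (nrow(spec@strata)) {
    spec@strata$yLoss <- 0
    spec@strata$xyDivergence <- 0
  }
  spec@populations$stratum2Extent <-
    ifelse(is.na(spec@populations$stratum2Extent), NA, 2.5e6)
  spec@populations$divergenceMultiplier <- 1
  spec
}

# Minimal genome for determinism/bookkeeping tests.
tinySpec <- function(seed = 1, ...) {
  args <- list(seed = seed, nAutosomes = 2, autosomeLength = 1e6,
    sexLength = 1e6, scaffoldLength = 1e5, sitesPerGene = 10,
    strata = data.frame(name = c("stratum1", "stratum2"),
      start = c(6e5, 3e5), end = c(8e5, 6e5),
      yLoss = c(0.5, 0), xyDivergence = c(0.05, 0.05)),
    upExtent = 3e5, downExtent = 2e5)
  over <- list(...)
  args[names(over)] <- over
  do.call(simSpec, args)
}

# lab-only per-gene log2 M:F SNP density (the SNP scan input) without
# simulating the wild populations
labSnpMF <- function(sim, spec, minCov = 10, minorFrac = 0.3) {
  flags <- callSnpSites(mapSitesToGenes(sim$sites, spec@genes),
    minCov, minorFrac)
  d <- suppressMessages(densityBySexPopulation(
    suppressMessages(geneSnpDensity(flags)), sim$samples))
  dm <- d[d$sex == "male", ]; df <- d[d$sex == "female", ]
  g <- intersect(dm$gene_id, df$gene_id)
  mf <- mfLog2Ratio(dm$density[match(g, dm$gene_id)],
                    df$density[match(g, df$gene_id)])
  out <- spec@genes[match(g, spec@genes$gene_id),
    c("gene_id", "chromosome", "position")]
  out$lab <- mf
  out
}

# build a WindowTrack directly from window means and a fixed band
makeTrack <- function(values, band, positions = NULL, window = 2L,
                      chromosome = "chr1") {
  nUnits <- length(values) + window - 1L
  if (is.null(positions)) positions <- as.numeric(seq_len(nUnits) * 1000)
  new("WindowTrack", chromosome = chromosome, unitPos = positions,
    window = as.integer(window), values = values,
    ciLow = band[1L], ciHigh = band[2L],
    significant = values < band[1L] | values > band[2L])
}
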