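# Upstream-vs-downstream contrasts and the autosomal-window permutation
# test of convergent X-Y divergence.

#' Wilcoxon rank-sum (Mann-Whitney U) test
#'
#' Exact enumeration when the pooled sample size is at most 16 and there are
#' no ties; otherwise the normal approximation with midrank tie handling and
#' continuity correction. \code{alternative = "greater"} tests x
#' stochastically greater than y.
#'
#' @param x,y Non-empty numeric samples.
#' @param alternative "greater", "less" or "two_sided".
#' @return list with \code{statistic} (U for x) and \code{p}.
#' @examples
#' wilcoxonRankSum(c(3, 4), c(1, 2), "greater")$p  # 1/6
#' @export
wilcoxonRankSum <- function(x, y, alternative = c("greater", "less", "two_sided")) {
  alternative <- match.arg(alternative)
  if (!length(x) || !length(y)) stopf("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- !ties && (length(x) + length(y)) <= 16L
  alt <- if (alternative == "two_sided") "two.sided" else alternative
  res <- suppressWarnings(
    wilcox.test(x, y, alternative = alt, exact = exact, correct = TRUE))
  list(statistic = unname(res$statistic), p = res$p.value)
}

#' Upstream-vs-downstream river contrast
#'
#' One-tailed Wilcoxon rank-sum P for the upstream per-gene normalized M:F
#' SNP densities being greater than the downstream ones, within a region.
#'
#' @param upValues,downValues Per-gene values restricted to the region.
#' @return One-tailed P-value.
#' @export
riverContrast <- function(upValues, downValues) {
  up <- upValues[is.finite(upValues)]
  dn <- downValues[is.finite(downValues)]
  if (!length(up) || !length(dn))
    stopf("river contrast needs genes in both populations")
  wilcoxonRankSum(up, dn, "greater")$p
}

#' Permutation test of convergent divergence over autosomal windows
#'
#' Tests whether the jointly significant upstream excess observed on the
#' focal sex-chromosome region could arise by chance in a random genomic
#' window. Each replicate draws a uniformly random \code{windowMb}-Mb
#' autosomal window (chromosome chosen proportional to its valid span,
#' start uniform). A window \emph{qualifies} iff (a) every river's
#' one-tailed up-greater-than-down Wilcoxon P is below \code{alpha} on the
#' genes in the window, and (b) the median lab M:F SNP density in the
#' window exceeds the upper bound of the autosomal 95\% confidence band.
#' Windows with fewer than \code{minGenes} usable genes for any river are
#' redrawn (counted). The empirical P is the qualifying fraction.
#'
#' @param geneStats data.frame with one row per gene: \code{gene_id},
#'   \code{chromosome}, \code{position} (bp), \code{lab} (lab M:F SNP
#'   density contrast), and for each river the columns
#'   \code{<river>_up} and \code{<river>_down} (normalized M:F densities
#'   relative to the lab female reference).
#' @param layout A [GenomeLayout-class] (identifies autosomes and lengths).
#' @param rivers Character vector of river names (>= 3 for the convergence
#'   design).
#' @param region Numeric \code{c(start, end)} of the focal region on the
#'   sex chromosome (bp).
#' @param windowMb Window size in Mb (default 10).
#' @param reps Number of sampled windows (default 1000).
#' @param alpha Per-river significance level (default 0.05).
#' @param seed RNG seed.
#' @param bandUpper Upper bound of the autosomal band for criterion (b);
#'   computed from the autosomal lab values via [autosomalBootstrapCI()]
#'   with \code{bandWindow} genes per replicate when NULL.
#' @param bandWindow Resample size for the band, matching the scan's
#'   window (default 40 genes).
#' @param estimator "plain" (qualifying/reps) or "add_one"
#'   ((qualifying+1)/(reps+1)).
#' @param minGenes Minimum usable genes per river per window (default 2).
#' @return A [ConvergenceResult-class].
#' @export
convergencePermutation <- function(geneStats, layout, rivers, region,
                                   windowMb = 10, reps = 1000L, alpha = 0.05,
                                   seed = 1L, bandUpper = NULL,
                                   estimator = c("plain", "add_one"),
                                   minGenes = 2L, bandWindow = 40L) {
  estimator <- match.arg(estimator)
  if (length(rivers) < 3L) stopf("convergence test needs >= 3 rivers")
  upCols <- paste0(rivers, "_up")
  dnCols <- paste0(rivers, "_down")
  need <- c("gene_id", "chromosome", "position", "lab", upCols, dnCols)
  if (!all(need %in% names(geneStats)))
    stopf("geneStats is missing columns: %s",
      paste(setdiff(need, names(geneStats)), collapse = ", "))

  ch <- chromosomeTable(layout)
  sexChr <- sexChromosome(layout)
  windowBp <- windowMb * 1e6
  autos <- ch[!ch$isSex & ch$length >= windowBp, , drop = FALSE]
  if (!nrow(autos)) stopf("no autosome is at least %g Mb long", windowMb)
  validSpan <- autos$length - windowBp

  # focal-region per-river contrasts
  onRegion <- geneStats$chromosome == sexChr &
    geneStats$position >= region[1L] & geneStats$position <= region[2L]
  if (!any(onRegion)) stopf("no genes in the focal region")
  perRiver <- vapply(seq_along(rivers), function(k) {
    riverContrast(geneStats[[upCols[k]]][onRegion],
                  geneStats[[dnCols[k]]][onRegion])
  }, numeric(1))
  names(perRiver) <- rivers

  isAuto <- geneStats$chromosome %in% autos$id
  if (is.null(bandUpper)) {
    labAuto <- geneStats$lab[isAuto & is.finite(geneStats$lab)]
    bandUpper <- autosomalBootstrapCI(labAuto, window = bandWindow,
      reps = reps, alpha = alpha, seed = deriveSeed(seed, "band"))[["high"]]
  }
  regionQualifies <- all(perRiver < alpha) &&
    median(geneStats$lab[onRegion], na.rm = TRUE) > bandUpper

  gs <- geneStats[isAuto, , drop = FALSE]
  nQ <- 0L; nRedraw <- 0L
  withSeed(deriveSeed(seed, "windows"), {
    maxDraws <- reps * 100L
    done <- 0L; draws <- 0L
    while (done < reps) {
      draws <- draws + 1L
      if (draws > maxDraws)
        stopf("too many window redraws: windows rarely contain %d genes per river",
          minGenes)
      ci <- sample.int(nrow(autos), 1L,
        prob = if (nrow(autos) > 1L) validSpan + 1 else NULL)
      s <- runif(1L, 0, validSpan[ci])
      inW <- gs$chromosome == autos$id[ci] & gs$position >= s &
        gs$position <= s + windowBp
      ok <- TRUE
      ps <- numeric(length(rivers))
      for (k in seq_along(rivers)) {
        up <- gs[[upCols[k]]][inW]; dn <- gs[[dnCols[k]]][inW]
        up <- up[is.finite(up)]; dn <- dn[is.finite(dn)]
        if (length(up) < minGenes || length(dn) < minGenes) { ok <- FALSE; break }
        ps[k] <- wilcoxonRankSum(up, dn, "greater")$p
      }
      if (!ok) { nRedraw <- nRedraw + 1L; next }
      done <- done + 1L
      if (all(ps < alpha) &&
          median(gs$lab[inW], na.rm = TRUE) > bandUpper)
        nQ <- nQ + 1L
    }
  })
  if (nRedraw > 0L)
    msgf("convergencePermutation: %d windows redrawn for sparse gene content", nRedraw)
  empP <- if (estimator == "plain") nQ / reps else (nQ + 1) / (reps + 1)
  new("ConvergenceResult", chromosome = sexChr,
    start = as.numeric(region[1L]), end = as.numeric(region[2L]),
    perRiverP = perRiver, regionQualifies = regionQualifies,
    nSampled = as.integer(reps), nQualifying = nQ, nRedraws = nRedraw,
    empiricalP = empP, bandUpper = as.numeric(bandUpper),
    seed = as.integer(seed))
}
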