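# Sliding-window scan: moving averages along ordered units, autosomal
# bootstrap confidence band, and stratum calling from runs of significant
# windows.

#' Moving average over a fixed window
#'
#' Plain sliding-window mean with step 1 and no partial windows:
#' \code{value[i] = mean(values[i .. i + window - 1])}. Computed as the
#' literal per-window arithmetic mean so results agree bit-for-bit with a
#' direct mean of each window.
#'
#' @param values Ordered numeric sequence.
#' @param window Window size in units (default 40).
#' @return Numeric vector of length \code{length(values) - window + 1}.
#' @examples
#' movingAverage(c(1, 2, 3, 4), 2)  # 1.5 2.5 3.5
#' @export
movingAverage <- function(values, window = 40L) {
  n <- length(values)
  window <- as.integer(window)
  if (window < 1L) stopf("window must be >= 1")
  if (window > n) stopf("window (%d) exceeds sequence length (%d)", window, n)
  vapply(seq_len(n - window + 1L),
    function(i) mean(values[i:(i + window - 1L)]), numeric(1))
}

#' Autosomal bootstrap confidence band for a window mean
#'
#' Draws \code{window} autosomal units without replacement, \code{reps}
#' times, records each replicate's mean, and returns the empirical
#' (alpha/2, 1 - alpha/2) percentiles: a single flat band describing the
#' null distribution of a window mean under autosomal exchangeability.
#'
#' @param autosomalValues Pool of per-unit autosomal values.
#' @param window Units per replicate (the scan's window size).
#' @param reps Bootstrap replicates (default 1000).
#' @param alpha Two-sided tail probability (default 0.05).
#' @param seed RNG seed.
#' @return Named numeric \code{c(low, high)}.
#' @export
autosomalBootstrapCI <- function(autosomalValues, window = 40L, reps = 1000L,
                                 alpha = 0.05, seed = 1L) {
  pool <- autosomalValues[is.finite(autosomalValues)]
  window <- as.integer(window)
  if (length(pool) < window)
    stopf("autosomal pool (%d) smaller than window (%d)", length(pool), window)
  assertNumber(alpha, "alpha", 0, 1)
  means <- withSeed(seed, vapply(seq_len(reps),
    function(i) mean(sample(pool, window, replace = FALSE)), numeric(1)))
  q <- quantile(means, c(alpha / 2, 1 - alpha / 2), names = FALSE)
  c(low = q[1L], high = q[2L])
}

#' Build a window track with significance against the autosomal band
#'
#' Runs [movingAverage()] over per-unit values ordered along a chromosome,
#' computes the flat autosomal bootstrap band, and flags windows whose mean
#' falls outside it.
#'
#' @param values Per-unit statistic for the scanned chromosome, ordered by
#'   position.
#' @param positions bp position of each unit (scaffold midpoint or gene
#'   position), sorted.
#' @param chromosome Chromosome id for the track.
#' @param autosomalValues Pool of the same per-unit statistic on autosomes.
#' @param window,reps,alpha,seed Passed to [movingAverage()] and
#'   [autosomalBootstrapCI()].
#' @return A [WindowTrack-class].
#' @export
buildWindowTrack <- function(values, positions, chromosome, autosomalValues,
                             window = 40L, reps = 1000L, alpha = 0.05,
                             seed = 1L) {
  if (length(values) != length(positions)) stopf("values and positions must align")
  o <- order(positions)
  values <- values[o]; positions <- positions[o]
  ma <- movingAverage(values, window)
  band <- autosomalBootstrapCI(autosomalValues, window, reps, alpha, seed)
  new("WindowTrack", chromosome = chromosome, unitPos = as.numeric(positions),
    window = as.integer(window), values = ma,
    ciLow = band[["low"]], ciHigh = band[["high"]],
    significant = ma < band[["low"]] | ma > band[["high"]])
}

#' Call candidate strata from runs of significant windows
#'
#' Maximal runs of at least \code{minRun} consecutive significant windows on
#' the informative side of the band become stratum calls: on a coverage
#' track, runs below the band (male coverage deficit); on a SNP-density
#' track, runs above it (male SNP excess). A call spans from the first unit
#' of its first window to the last unit of its last window.
#'
#' @param track A [WindowTrack-class].
#' @param statistic "coverage" (deficit = below band) or "snp_density"
#'   (excess = above band).
#' @param minRun Minimum run length in windows (default 5).
#' @return A [GenomicRanges::GRanges] with metadata columns
#'   \code{evidence} and \code{nWindows}; empty when no run qualifies.
#' @export
callStrata <- function(track, statistic = c("coverage", "snp_density"),
                       minRun = 5L) {
  statistic <- match.arg(statistic)
  validObject(track)
  evid <- if (statistic == "coverage") "coverage_deficit" else "snp_excess"
  hit <- if (statistic == "coverage") track@values < track@ciLow
         else track@values > track@ciHigh
  empty <- GRanges(character(), IRanges(integer(), integer()),
    evidence = character(), nWindows = integer())
  if (!length(hit) || !any(hit)) return(empty)
  r <- rle(hit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= minRun
  if (!any(keep)) return(empty)
  w <- track@window
  first <- starts[keep]
  last <- ends[keep]
  GRanges(track@chromosome,
    IRanges(start = round(track@unitPos[first]),
            end = round(track@unitPos[last + w - 1L])),
    evidence = evid, nWindows = r$lengths[keep])
}
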