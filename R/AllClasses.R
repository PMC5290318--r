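#' GenomeLayout: scaffold-to-chromosome assignments
#'
#' Holds the ordered placement of assembly scaffolds along reference
#' chromosomes, the coordinate frame for every windowed statistic. At most
#' one chromosome may be flagged as the sex chromosome.
#'
#' @slot chromosomes data.frame with columns \code{id}, \code{length} (bp),
#'   \code{isSex} (logical; at most one TRUE).
#' @slot scaffolds data.frame with columns \code{scaffold_id},
#'   \code{chromosome}, \code{chromStart}, \code{chromEnd} (1-based inclusive
#'   bp on the chromosome). Scaffold intervals on one chromosome must not
#'   overlap.
#'
#' @seealso [assignScaffolds()], [simLayout()]
#' @exportClass GenomeLayout
setClass("GenomeLayout",
  representation(chromosomes = "data.frame", scaffolds = "data.frame"))

setValidity("GenomeLayout", function(object) {
  ch <- object@chromosomes
  sc <- object@scaffolds
  need <- c("id", "length", "isSex")
  if (!all(need %in% names(ch)))
    return(sprintf("chromosomes must have columns %s", paste(need, collapse = ", ")))
  need <- c("scaffold_id", "chromosome", "chromStart", "chromEnd")
  if (!all(need %in% names(sc)))
    return(sprintf("scaffolds must have columns %s", paste(need, collapse = ", ")))
  if (anyDuplicated(ch$id)) return("duplicate chromosome ids")
  if (sum(ch$isSex) > 1L) return("at most one chromosome may be the sex chromosome")
  if (nrow(sc)) {
    if (anyDuplicated(sc$scaffold_id)) return("duplicate scaffold ids")
    if (!all(sc$chromosome %in% ch$id)) return("scaffold on unknown chromosome")
    if (any(sc$chromStart < 1L) || any(sc$chromEnd < sc$chromStart))
      return("scaffold intervals must satisfy 1 <= chromStart <= chromEnd")
    len <- ch$length[match(sc$chromosome, ch$id)]
    if (any(sc$chromEnd > len)) return("scaffold interval exceeds chromosome length")
    bad <- vapply(split(sc, sc$chromosome), function(d) {
      d <- d[order(d$chromStart), ]
      nrow(d) > 1L && any(d$chromStart[-1L] <= d$chromEnd[-nrow(d)])
    }, logical(1))
    if (any(bad)) return("overlapping scaffolds on one chromosome")
  }
  TRUE
})

#' @describeIn GenomeLayout-class chromosome table accessor
#' @param layout A \code{GenomeLayout}.
#' @export
chromosomeTable <- function(layout) layout@chromosomes

#' @describeIn GenomeLayout-class scaffold placement accessor
#' @export
scaffoldTable <- function(layout) layout@scaffolds

#' @describeIn GenomeLayout-class id of the sex chromosome (or NA)
#' @export
sexChromosome <- function(layout) {
  ch <- layout@chromosomes
  if (any(ch$isSex)) ch$id[ch$isSex][1L] else NA_character_
}

setMethod("show", "GenomeLayout", function(object) {
  ch <- object@chromosomes
  cat(sprintf("GenomeLayout: %d chromosomes (%s), %d scaffolds\n",
    nrow(ch),
    if (any(ch$isSex)) paste0("sex = ", sexChromosome(object)) else "no sex chromosome",
    nrow(object@scaffolds)))
})

#' GenomeLayout constructor
#'
#' @param chromosomes data.frame of \code{id}, \code{length}, \code{isSex}.
#' @param scaffolds data.frame of \code{scaffold_id}, \code{chromosome},
#'   \code{chromStart}, \code{chromEnd}.
#' @return A validated [GenomeLayout-class] object.
#' @export
GenomeLayout <- function(chromosomes, scaffolds) {
  new("GenomeLayout",
    chromosomes = as.data.frame(chromosomes),
    scaffolds = as.data.frame(scaffolds))
}

#' WindowTrack: moving-average scan with bootstrap confidence band
#'
#' Ordered sliding-window means of a per-unit statistic (units are scaffolds
#' for coverage, genes for SNP density or expression) together with the flat
#' 95\% autosomal bootstrap band and a per-window significance flag.
#'
#' Window i spans units i .. i+window-1; its reported position is the
#' midpoint of the spanned unit positions. A window is significant exactly
#' when its mean lies outside \[ciLow, ciHigh\].
#'
#' @slot chromosome Chromosome the scanned units lie on.
#' @slot unitPos Numeric, bp position of each ordered unit.
#' @slot window Integer window size in units.
#' @slot values Moving means, length \code{length(unitPos) - window + 1}.
#' @slot ciLow,ciHigh Flat band endpoints (scalars).
#' @slot significant Logical per window.
#' @seealso [buildWindowTrack()], [callStrata()], [writeTrack()]
#' @exportClass WindowTrack
setClass("WindowTrack", representation(
  chromosome = "character", unitPos = "numeric", window = "integer",
  values = "numeric", ciLow = "numeric", ciHigh = "numeric",
  significant = "logical"))

setValidity("WindowTrack", function(object) {
  n <- length(object@unitPos)
  w <- object@window
  if (length(w) != 1L || w < 1L) return("window must be a positive integer")
  if (n > 0L && w > n) return("window larger than number of units")
  if (is.unsorted(object@unitPos)) return("unit positions must be sorted")
  if (length(object@values) != max(0L, n - w + 1L))
    return("length(values) must equal n_units - window + 1")
  if (length(object@significant) != length(object@values))
    return("significant flag per window required")
  if (length(object@ciLow) != 1L || length(object@ciHigh) != 1L)
    return("band endpoints must be scalars")
  if (object@ciLow > object@ciHigh) return("ciLow must be <= ciHigh")
  sig <- object@values < object@ciLow | object@values > object@ciHigh
  if (!identical(sig, object@significant))
    return("significant must mark exactly the windows outside the band")
  TRUE
})

setMethod("show", "WindowTrack", function(object) {
  cat(sprintf(
    "WindowTrack on %s: %d units, window %d -> %d windows\n  band [%.4g, %.4g], %d significant\n",
    object@chromosome, length(object@unitPos), object@window,
    length(object@values), object@ciLow, object@ciHigh, sum(object@significant)))
})

#' @describeIn WindowTrack-class moving-average values
#' @param track A \code{WindowTrack}.
#' @export
trackValues <- function(track) track@values

#' @describeIn WindowTrack-class flat confidence band \code{c(low, high)}
#' @export
trackBand <- function(track) c(low = track@ciLow, high = track@ciHigh)

#' @describeIn WindowTrack-class logical significance flags per window
#' @export
significantWindows <- function(track) track@significant

#' @describeIn WindowTrack-class midpoint (bp) of each window's spanned units
#' @export
windowMidpoints <- function(track) {
  w <- track@window
  n <- length(track@values)
  (track@unitPos[seq_len(n)] + track@unitPos[seq_len(n) + w - 1L]) / 2
}

#' SimSpec: full parameterization of the synthetic study
#'
#' Bundles the genome layout, stratum effect sizes, sequencing model,
#' population design, expression model and ortholog divergence model under a
#' single master seed. Construct with [simSpec()].
#'
#' @slot seed Master RNG seed.
#' @slot layout [GenomeLayout-class] with one sex chromosome.
#' @slot genes data.frame of gene models (one per scaffold).
#' @slot strata data.frame: \code{name}, \code{start}, \code{end} (bp on the
#'   sex chromosome), \code{yLoss} (delta, fraction of Y-derived reads lost),
#'   \code{xyDivergence} (rho, per-site fixed X-Y difference probability).
#' @slot pi Baseline per-site heterozygosity (both sexes, everywhere).
#' @slot depth Mean per-site coverage.
#' @slot dispersion Negative-binomial size parameter (variance =
#'   mu + mu^2/dispersion; large values approach Poisson).
#' @slot nPerSex Individuals per present sex per population.
#' @slot sitesPerGene Profiled sites per gene.
#' @slot populations data.frame: \code{name}, \code{river}, \code{role}
#'   (lab/up/down), \code{stratum2Extent} (bp), \code{divergenceMultiplier}.
#' @slot expression list(logMean, logSd, biasFraction, biasMagnitude, libSize).
#' @slot orthologs list(nPerCategory, nSites, sSites, dN, dS) with dN, dS
#'   named by category.
#' @exportClass SimSpec
setClass("SimSpec", representation(
  seed = "integer", layout = "GenomeLayout", genes = "data.frame",
  strata = "data.frame", pi = "numeric", depth = "numeric",
  dispersion = "numeric", nPerSex = "integer", sitesPerGene = "integer",
  populations = "data.frame", expression = "list", orthologs = "list"))

setValidity("SimSpec", function(object) {
  st <- object@strata
  if (nrow(st)) {
    if (!all(c("name", "start", "end", "yLoss", "xyDivergence") %in% names(st)))
      return("strata needs columns name,start,end,yLoss,xyDivergence")
    if (any(st$yLoss < 0 | st$yLoss > 1)) return("yLoss must lie in [0,1]")
    if (any(st$xyDivergence < 0 | st$xyDivergence > 1))
      return("xyDivergence must lie in [0,1]")
    if (any(st$end <= st$start)) return("stratum end must exceed start")
    sx <- sexChromosome(object@layout)
    if (is.na(sx)) return("strata require a sex chromosome in the layout")
    len <- object@layout@chromosomes$length[object@layout@chromosomes$id == sx]
    if (any(st$start < 0 | st$end > len))
      return("stratum interval outside the sex chromosome")
  }
  if (object@pi < 0 || object@pi > 1) return("pi must lie in [0,1]")
  if (object@depth <= 0) return("depth must be positive")
  if (object@dispersion <= 0) return("dispersion must be positive")
  if (object@nPerSex < 1L) return("nPerSex must be >= 1")
  if (object@sitesPerGene < 1L) return("sitesPerGene must be >= 1")
  po <- object@populations
  if (!all(c("name", "river", "role", "stratum2Extent", "divergenceMultiplier") %in% names(po)))
    return("populations needs columns name,river,role,stratum2Extent,divergenceMultiplier")
  if (!all(po$role %in% c("lab", "up", "down"))) return("population role must be lab/up/down")
  if (any(po$divergenceMultiplier < 0)) return("divergenceMultiplier must be >= 0")
  TRUE
})

setMethod("show", "SimSpec", function(object) {
  cat(sprintf(
    "SimSpec (seed %d): %d genes on %d chromosomes, depth %g (NB size %g), pi %g\n",
    object@seed, nrow(object@genes), nrow(object@layout@chromosomes),
    object@depth, object@dispersion, object@pi))
  if (nrow(object@strata))
    for (i in seq_len(nrow(object@strata)))
      cat(sprintf("  %s: %.1f-%.1f Mb, delta=%g, rho=%g\n",
        object@strata$name[i], object@strata$start[i] / 1e6,
        object@strata$end[i] / 1e6, object@strata$yLoss[i],
        object@strata$xyDivergence[i]))
  cat(sprintf("  populations: %s\n", paste(object@populations$name, collapse = ", ")))
})

#' ConvergenceResult: permutation test of convergent X-Y divergence
#'
#' Result of [convergencePermutation()]: per-river one-tailed Wilcoxon
#' P-values for the focal sex-chromosome region, and the empirical
#' probability that a random autosomal window of the same physical size
#' satisfies the full qualification criterion (all rivers P < alpha and the
#' lab median above the autosomal band).
#'
#' @slot chromosome,start,end The focal region tested.
#' @slot perRiverP Named one-tailed Wilcoxon P per river on the focal region.
#' @slot regionQualifies Whether the focal region itself meets the criterion.
#' @slot nSampled,nQualifying Autosomal windows sampled / qualifying.
#' @slot nRedraws Windows redrawn for having too few genes.
#' @slot empiricalP Qualifying fraction (estimator-dependent).
#' @slot bandUpper Upper bound of the autosomal 95\% band used in criterion (b).
#' @slot seed RNG seed used.
#' @exportClass ConvergenceResult
setClass("ConvergenceResult", representation(
  chromosome = "character", start = "numeric", end = "numeric",
  perRiverP = "numeric", regionQualifies = "logical",
  nSampled = "integer", nQualifying = "integer", nRedraws = "integer",
  empiricalP = "numeric", bandUpper = "numeric", seed = "integer"))

setValidity("ConvergenceResult", function(object) {
  if (object@empiricalP < 0 || object@empiricalP > 1)
    return("empiricalP must lie in [0,1]")
  if (any(object@perRiverP <= 0 | object@perRiverP > 1))
    return("per-river P values must lie in (0,1]")
  TRUE
})

setMethod("show", "ConvergenceResult", function(object) {
  cat(sprintf("ConvergenceResult for %s:%.1f-%.1f Mb\n", object@chromosome,
    object@start / 1e6, object@end / 1e6))
  cat("  per-river one-tailed Wilcoxon P:",
    paste(sprintf("%s=%.4g", names(object@perRiverP), object@perRiverP),
      collapse = ", "), "\n")
  cat(sprintf("  region qualifies: %s\n", object@regionQualifies))
  cat(sprintf("  autosomal windows: %d qualifying / %d sampled (%d redraws) -> empirical P = %.4g\n",
    object@nQualifying, object@nSampled, object@nRedraws, object@empiricalP))
})

#' @describeIn ConvergenceResult-class empirical P accessor
#' @param x A \code{ConvergenceResult}.
#' @export
empiricalP <- function(x) x@empiricalP

#' @describeIn ConvergenceResult-class per-river Wilcoxon P accessor
#' @export
perRiverP <- function(x) x@perRiverP
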