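# Per-scaffold coverage, per-gene SNP density and expression statistics,
# and their male:female log2 contrasts.

#' log2 male:female contrast with pseudocount
#'
#' \code{log2(m + pseudocount) - log2(f + pseudocount)}. The +1 pseudocount
#' is applied to the value being logged (mean coverage, per-gene density,
#' mean RPKM) to keep the contrast finite at zero.
#'
#' @param m,f Non-negative male and female summary values (vectorized).
#' @param pseudocount Added to each value before logging (default 1).
#' @return log2 contrast, antisymmetric in (m, f).
#' @examples
#' mfLog2Ratio(3, 1)  # log2(4) - log2(2) = 1
#' mfLog2Ratio(0, 0)  # 0: pseudocount floor
#' @export
mfLog2Ratio <- function(m, f, pseudocount = 1) {
  if (any(m < 0, na.rm = TRUE) || any(f < 0, na.rm = TRUE))
    stopf("mfLog2Ratio: inputs must be non-negative")
  log2(m + pseudocount) - log2(f + pseudocount)
}

#' Per-scaffold per-sample mean coverage
#'
#' Coverage of a scaffold in a sample is the total number of times its sites
#' were sequenced divided by the number of sites that were sequenced; sites
#' with zero reads count as not sequenced and are excluded from the
#' denominator. (scaffold, sample) pairs with no sequenced site are flagged
#' missing and excluded with a message.
#'
#' @param sites Site-count table ([readSiteCounts()] / simulator output).
#' @return data.frame with \code{scaffold_id}, \code{sample_id},
#'   \code{coverage}, \code{nSites}.
#' @export
scaffoldCoverage <- function(sites) {
  dt <- data.table::as.data.table(sites)
  if (!"coverage" %in% names(dt)) dt[, coverage := A + C + G + T]
  res <- dt[, .(coverage = {
    seqd <- coverage[coverage > 0]
    if (length(seqd)) mean(seqd) else NA_real_
  }, nSites = sum(coverage > 0)), by = .(scaffold_id, sample_id)]
  miss <- res$nSites == 0L
  if (any(miss))
    msgf("scaffoldCoverage: %d scaffold/sample pairs with no sequenced site dropped",
      sum(miss))
  as.data.frame(res[!miss])
}

#' Per-scaffold log2 M:F coverage contrast
#'
#' Averages per-sample scaffold coverage within each sex, then forms the
#' pseudocounted log2 male:female ratio per scaffold.
#'
#' @param covTable Output of [scaffoldCoverage()].
#' @param samples Sample sheet (sample_id, sex).
#' @param pseudocount Passed to [mfLog2Ratio()].
#' @return data.frame \code{scaffold_id}, \code{maleMean},
#'   \code{femaleMean}, \code{log2MF}.
#' @export
coverageContrast <- function(covTable, samples, pseudocount = 1) {
  dt <- data.table::as.data.table(covTable)
  dt[, sex := samples$sex[match(sample_id, samples$sample_id)]]
  if (anyNA(dt$sex)) stopf("coverage table contains samples absent from the sample sheet")
  wide <- dt[, .(m = mean(coverage[sex == "male"]),
                 f = mean(coverage[sex == "female"])), by = scaffold_id]
  wide <- wide[is.finite(m) & is.finite(f)]
  data.frame(scaffold_id = wide$scaffold_id, maleMean = wide$m,
    femaleMean = wide$f, log2MF = mfLog2Ratio(wide$m, wide$f, pseudocount))
}

# second-largest of four count columns, vectorized
.secondMax <- function(a, b, c, d) {
  M1 <- pmax(a, b); M2 <- pmax(c, d)
  m1 <- pmin(a, b); m2 <- pmin(c, d)
  pmax(pmin(M1, M2), ifelse(M1 >= M2, m1, m2))
}

#' Call SNP sites from allele counts
#'
#' Sites with coverage below \code{minCov} (default 10) are excluded from
#' both the SNP count and the site denominator. Among retained sites a SNP
#' is called when the second-most-frequent allele count is at least
#' \code{minorFrac} times the site coverage (equivalently, the major-allele
#' fraction is at most 1 - minorFrac).
#'
#' @param sites Site-count table.
#' @param minCov Minimum coverage to retain a site (>= 1).
#' @param minorFrac Minor-allele fraction threshold in (0, 0.5].
#' @return The table with added logical columns \code{retained} and
#'   \code{snp} (FALSE for non-retained sites).
#' @examples
#' s <- data.frame(scaffold_id = "s", pos = 1:3, sample_id = "M1",
#'   A = c(5, 8, 6), C = c(5, 2, 3), G = 0, T = 0)
#' callSnpSites(s)[, c("retained", "snp")]
#' @export
callSnpSites <- function(sites, minCov = 10, minorFrac = 0.3) {
  if (!is.numeric(minCov) || minCov < 1) stopf("minCov must be >= 1")
  if (!is.numeric(minorFrac) || minorFrac <= 0 || minorFrac > 0.5)
    stopf("minorFrac must lie in (0, 0.5]")
  dt <- data.table::as.data.table(sites)
  if (any(dt$A < 0 | dt$C < 0 | dt$G < 0 | dt$T < 0)) stopf("negative allele count")
  dt[, coverage := A + C + G + T]
  dt[, retained := coverage >= minCov]
  dt[, snp := retained & .secondMax(A, C, G, T) >= minorFrac * coverage]
  dt[]
}

#' Map sites to genes by interval overlap
#'
#' Restricts a site table to sites falling inside gene models on the same
#' scaffold (SNPs are only counted within genic regions).
#'
#' @param sites Site table (needs \code{scaffold_id}, \code{pos}).
#' @param genes Gene table with \code{gene_id}, \code{scaffold_id},
#'   \code{start}, \code{end} (1-based inclusive).
#' @return The genic subset of \code{sites} with a \code{gene_id} column.
#' @export
mapSitesToGenes <- function(sites, genes) {
  dt <- data.table::as.data.table(sites)
  g <- data.table::as.data.table(genes)[, .(gene_id, scaffold_id, start, end)]
  dt[, `:=`(s0 = pos, e0 = pos)]
  data.table::setkey(g, scaffold_id, start, end)
  ov <- data.table::foverlaps(dt, g, by.x = c("scaffold_id", "s0", "e0"),
    nomatch = NULL)
  ov[, c("s0", "e0", "start", "end") := NULL]
  ov[]
}

#' Per-gene per-individual SNP density
#'
#' Density is the number of SNP sites over the number of coverage-filtered
#' sites in the gene for that individual. Genes with zero filtered sites
#' are excluded (with a message).
#'
#' @param flaggedSites Output of [callSnpSites()] restricted to genic sites
#'   (i.e. carrying a \code{gene_id} column; see [mapSitesToGenes()]).
#' @return data.frame \code{gene_id}, \code{sample_id}, \code{nFiltered},
#'   \code{nSnp}, \code{density}.
#' @export
geneSnpDensity <- function(flaggedSites) {
  dt <- data.table::as.data.table(flaggedSites)
  if (!"gene_id" %in% names(dt))
    stopf("flaggedSites must carry gene_id (use mapSitesToGenes)")
  all <- dt[, .(nFiltered = sum(retained), nSnp = sum(snp)),
    by = .(gene_id, sample_id)]
  dropped <- all[nFiltered == 0L]
  if (nrow(dropped))
    msgf("geneSnpDensity: %d gene/sample pairs with zero filtered sites dropped",
      nrow(dropped))
  res <- all[nFiltered > 0L]
  res[, density := nSnp / nFiltered]
  as.data.frame(res)
}

#' Average SNP density per gene within population and sex
#'
#' Default is the mean of per-individual densities (densities are averaged
#' separately within each population); \code{method = "pooled"} instead
#' pools SNP and filtered-site counts across individuals before dividing.
#'
#' @param geneDensity Output of [geneSnpDensity()].
#' @param samples Sample sheet (sample_id, sex, population).
#' @param method "mean" (default) or "pooled".
#' @return data.frame \code{gene_id}, \code{population}, \code{sex},
#'   \code{density}, \code{n} (individuals contributing).
#' @export
densityBySexPopulation <- function(geneDensity, samples,
                                   method = c("mean", "pooled")) {
  method <- match.arg(method)
  dt <- data.table::as.data.table(geneDensity)
  m <- match(dt$sample_id, samples$sample_id)
  if (anyNA(m)) stopf("density table contains samples absent from the sample sheet")
  dt[, `:=`(sex = samples$sex[m], population = samples$population[m])]
  res <- if (method == "mean") {
    dt[, .(density = mean(density), n = .N), by = .(gene_id, population, sex)]
  } else {
    dt[, .(density = sum(nSnp) / sum(nFiltered), n = .N),
      by = .(gene_id, population, sex)]
  }
  as.data.frame(res)
}

#' Normalize per-gene log2 values by the X-chromosome median
#'
#' Subtracts the median of the sex-chromosome (X-linked) values of the same
#' population and sex from every value, putting populations with different
#' sequencing depth or diversity on a common scale; the normalized X median
#' is exactly zero.
#'
#' @param values Numeric per-gene log2 values.
#' @param isX Logical, TRUE for X-linked genes.
#' @return Normalized values.
#' @export
normalizeByXMedian <- function(values, isX) {
  if (length(values) != length(isX)) stopf("values and isX must align")
  if (!any(isX)) stopf("no X-linked genes to normalize by")
  values - median(values[isX], na.rm = TRUE)
}

#' Express normalized values relative to a reference (lab female) set
#'
#' Subtracts the reference's normalized value gene by gene, on the shared
#' gene set only; genes absent from either side are dropped with a message.
#'
#' @param popValues,refValues Named numeric vectors (names = gene ids).
#' @return Named numeric vector on the intersection of gene sets.
#' @export
relativeToReference <- function(popValues, refValues) {
  shared <- intersect(names(popValues), names(refValues))
  if (!length(shared)) stopf("no shared genes between population and reference")
  dropped <- length(popValues) - length(shared)
  if (dropped > 0L)
    msgf("relativeToReference: %d genes absent from the reference dropped", dropped)
  popValues[shared] - refValues[shared]
}

#' RPKM from a count matrix
#'
#' RPKM = count / (length/1e3) / (librarySize/1e6). Library sizes default
#' to the column sums of the retained-gene count matrix.
#'
#' @param counts Gene x sample matrix of read counts.
#' @param lengths Exonic lengths (bp), recycled along rows; named vectors
#'   are matched to rownames.
#' @param librarySizes Optional per-sample library sizes.
#' @return RPKM matrix of the same shape.
#' @examples
#' rpkm(matrix(10, 1, 1), lengths = 1000, librarySizes = 1e6)  # 10
#' @export
rpkm <- function(counts, lengths, librarySizes = colSums(counts)) {
  counts <- as.matrix(counts)
  if (!is.null(names(lengths)) && !is.null(rownames(counts)))
    lengths <- lengths[rownames(counts)]
  if (any(lengths < 1)) stopf("gene lengths must be >= 1")
  if (any(librarySizes <= 0)) stopf("library sizes must be positive")
  sweep(counts / (lengths / 1e3), 2L, librarySizes / 1e6, "/")
}

#' Minimum-expression filter
#'
#' Keeps a gene iff at least half of the individuals of either sex (ceiling
#' for odd counts) reach \code{threshold} RPKM.
#'
#' @param rpkmMat RPKM matrix (genes x samples).
#' @param samples Sample sheet with \code{sample_id}, \code{sex}.
#' @param threshold Expression threshold (default 2).
#' @return Character vector of retained gene ids.
#' @export
expressionFilter <- function(rpkmMat, samples, threshold = 2) {
  sex <- samples$sex[match(colnames(rpkmMat), samples$sample_id)]
  males <- which(sex == "male"); females <- which(sex == "female")
  if (!length(males) || !length(females))
    stopf("both sexes must be present for the expression filter")
  okM <- rowSums(rpkmMat[, males, drop = FALSE] >= threshold) >= ceiling(length(males) / 2)
  okF <- rowSums(rpkmMat[, females, drop = FALSE] >= threshold) >= ceiling(length(females) / 2)
  rownames(rpkmMat)[okM | okF]
}

#' Per-gene sex-averaged expression and log2 M:F contrast
#'
#' @param rpkmMat RPKM matrix (genes x samples).
#' @param samples Sample sheet with \code{sample_id}, \code{sex}.
#' @param pseudocount Passed to [mfLog2Ratio()].
#' @return data.frame \code{gene_id}, \code{maleRpkm}, \code{femaleRpkm},
#'   \code{log2MF}.
#' @export
expressionSummary <- function(rpkmMat, samples, pseudocount = 1) {
  sex <- samples$sex[match(colnames(rpkmMat), samples$sample_id)]
  m <- rowMeans(rpkmMat[, sex == "male", drop = FALSE])
  f <- rowMeans(rpkmMat[, sex == "female", drop = FALSE])
  data.frame(gene_id = rownames(rpkmMat), maleRpkm = m, femaleRpkm = f,
    log2MF = mfLog2Ratio(m, f, pseudocount))
}
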