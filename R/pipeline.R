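# End-to-end orchestration: in-memory analysis chain plus file-based stages
# with manifests, and a run-all mode reproducing the full synthetic
# experiment.

#' Coverage scan for one population
#'
#' Per-scaffold mean coverage by sample, sex-averaged log2 M:F contrast,
#' moving-average track on the sex chromosome against the autosomal
#' bootstrap band, and stratum calls from runs of significant windows.
#'
#' @param sites Site-count table (both sexes).
#' @param samples Sample sheet.
#' @param layout A [GenomeLayout-class] with a sex chromosome.
#' @param window,reps,alpha,seed Scan parameters (see [buildWindowTrack()]).
#' @param pseudocount Passed to [mfLog2Ratio()].
#' @param minRun Minimum significant-window run for a call.
#' @return list with \code{contrast} (per-scaffold table with chromosome
#'   positions), \code{track} ([WindowTrack-class]) and \code{calls}
#'   (GRanges from [callStrata()]).
#' @export
coverageScan <- function(sites, samples, layout, window = 40L, reps = 1000L,
                         alpha = 0.05, seed = 1L, pseudocount = 1,
                         minRun = 5L) {
  cc <- coverageContrast(scaffoldCoverage(sites), samples, pseudocount)
  sc <- scaffoldTable(layout)
  m <- match(cc$scaffold_id, sc$scaffold_id)
  if (anyNA(m)) stopf("coverage table contains scaffolds absent from the layout")
  cc$chromosome <- sc$chromosome[m]
  cc$position <- (sc$chromStart[m] + sc$chromEnd[m]) / 2
  sexChr <- sexChromosome(layout)
  if (is.na(sexChr)) stopf("layout has no sex chromosome")
  onX <- cc$chromosome == sexChr
  track <- buildWindowTrack(cc$log2MF[onX], cc$position[onX], sexChr,
    cc$log2MF[!onX], window, reps, alpha, deriveSeed(seed, "cov_band"))
  list(contrast = cc, track = track,
    calls = callStrata(track, "coverage", minRun))
}

# per-population per-sex per-gene mean SNP density
.popGeneDensity <- function(sites, samples, genes, minCov, minorFrac,
                            densityMethod) {
  flags <- callSnpSites(mapSitesToGenes(sites, genes), minCov, minorFrac)
  densityBySexPopulation(geneSnpDensity(flags), samples, densityMethod)
}

#' Per-gene SNP-density statistics across populations
#'
#' Computes per-gene per-population mean SNP densities, the lab log2 M:F
#' contrast, and for each wild (male-only) population its X-median
#' normalized log2 density expressed relative to the normalized lab-female
#' reference. The result is the gene table consumed by [snpScan()] and
#' [convergencePermutation()].
#'
#' @param sims Named list of population datasets, each with \code{sites}
#'   and \code{samples} (as produced by [simulatePopulations()], or
#'   assembled from [readSiteCounts()] output).
#' @param genes Gene table with \code{gene_id}, \code{scaffold_id},
#'   \code{start}, \code{end}, \code{chromosome}, \code{position}.
#' @param layout A [GenomeLayout-class].
#' @param minCov,minorFrac SNP-calling parameters.
#' @param pseudocount Added before log2.
#' @param densityMethod "mean" or "pooled" (see [densityBySexPopulation()]).
#' @return list with \code{geneStats} (gene_id, chromosome, position, lab,
#'   one column per wild population) and \code{rivers} (river names with a
#'   complete up/down pair).
#' @export
snpGeneStats <- function(sims, genes, layout, minCov = 10, minorFrac = 0.3,
                         pseudocount = 1, densityMethod = "mean") {
  if (!"lab" %in% names(sims)) stopf("sims must include the lab population")
  sexChr <- sexChromosome(layout)
  isXGene <- setNames(genes$chromosome == sexChr, genes$gene_id)

  dens <- lapply(names(sims), function(p)
    .popGeneDensity(sims[[p]]$sites, sims[[p]]$samples, genes, minCov,
      minorFrac, densityMethod))
  names(dens) <- names(sims)

  lab <- dens[["lab"]]
  labM <- setNames(lab$density[lab$sex == "male"], lab$gene_id[lab$sex == "male"])
  labF <- setNames(lab$density[lab$sex == "female"], lab$gene_id[lab$sex == "female"])
  shared <- intersect(names(labM), names(labF))
  labMF <- setNames(mfLog2Ratio(labM[shared], labF[shared], pseudocount), shared)
  labFNorm <- normalizeByXMedian(log2(labF + pseudocount), isXGene[names(labF)])

  geneStats <- data.frame(gene_id = genes$gene_id,
    chromosome = genes$chromosome, position = genes$position)
  geneStats$lab <- labMF[match(geneStats$gene_id, names(labMF))]

  for (p in setdiff(names(sims), "lab")) {
    d <- dens[[p]]
    d <- d[d$sex == "male", , drop = FALSE]
    v <- setNames(d$density, d$gene_id)
    vNorm <- normalizeByXMedian(log2(v + pseudocount), isXGene[names(v)])
    contrast <- relativeToReference(vNorm, labFNorm)
    geneStats[[p]] <- contrast[match(geneStats$gene_id, names(contrast))]
  }
  po <- unique(sub("_(up|down)$", "", setdiff(names(sims), "lab")))
  rivers <- po[paste0(po, "_up") %in% names(sims) &
               paste0(po, "_down") %in% names(sims)]
  list(geneStats = geneStats, rivers = rivers)
}

#' SNP-density scan on the sex chromosome
#'
#' Moving average of the lab per-gene log2 M:F SNP density along the sex
#' chromosome against the autosomal bootstrap band, with stratum calls
#' for runs of male SNP excess.
#'
#' @param geneStats Gene table from [snpGeneStats()].
#' @param layout A [GenomeLayout-class].
#' @param window,reps,alpha,seed,minRun Scan parameters.
#' @return list with \code{track} and \code{calls}.
#' @export
snpScan <- function(geneStats, layout, window = 40L, reps = 1000L,
                    alpha = 0.05, seed = 1L, minRun = 5L) {
  sexChr <- sexChromosome(layout)
  ok <- is.finite(geneStats$lab)
  onX <- ok & geneStats$chromosome == sexChr
  track <- buildWindowTrack(geneStats$lab[onX], geneStats$position[onX],
    sexChr, geneStats$lab[ok & !onX], window, reps, alpha,
    deriveSeed(seed, "snp_band"))
  list(track = track, calls = callStrata(track, "snp_density", minRun))
}

#' Assemble a pipeline configuration
#'
#' Bundles the synthetic-study spec, all stage parameters and the output
#' directory. Every stochastic stage derives its stream from the single
#' \code{seed}.
#'
#' @param outDir Output directory (created on demand).
#' @param seed Global seed.
#' @param spec A [SimSpec-class]; built as \code{simSpec(seed = seed,
#'   ...simArgs)} when NULL.
#' @param simArgs list of overrides passed to [simSpec()] when building.
#' @param window,reps,alpha Scan parameters.
#' @param minCov,minorFrac,pseudocount SNP/contrast parameters.
#' @param fpkmThreshold Expression filter threshold.
#' @param minRun Stratum-call run length.
#' @param windowMb,estimator Convergence-test parameters.
#' @param region Focal region \code{c(start, end)} bp on the sex chromosome.
#' @param minLen,maxDs Ortholog filters.
#' @param densityMethod Per-population density averaging.
#' @param stages Stages to run in [runAll()].
#' @return A named list of validated parameters (class
#'   \code{"PipelineConfig"}).
#' @export
pipelineConfig <- function(outDir = file.path(tempdir(), "strataScan_run"),
                           seed = 1L, spec = NULL, simArgs = list(),
                           window = 40L, reps = 1000L, alpha = 0.05,
                           minCov = 10, minorFrac = 0.3, pseudocount = 1,
                           fpkmThreshold = 2, minRun = 5L, windowMb = 10,
                           estimator = "plain", region = c(15e6, 25e6),
                           minLen = 300, maxDs = 2, densityMethod = "mean",
                           stages = c("simulate", "coverage", "snpdensity",
                             "expression", "scan", "converge", "fasterx")) {
  assertNumber(alpha, "alpha", 0, 1)
  assertNumber(windowMb, "windowMb", 0.001, Inf)
  assertNumber(minCov, "minCov", 1, Inf)
  assertNumber(minorFrac, "minorFrac", 1e-9, 0.5)
  if (is.null(spec)) spec <- do.call(simSpec, c(list(seed = seed), simArgs))
  cfg <- list(outDir = outDir, seed = as.integer(seed), spec = spec,
    window = as.integer(window), reps = as.integer(reps), alpha = alpha,
    minCov = minCov, minorFrac = minorFrac, pseudocount = pseudocount,
    fpkmThreshold = fpkmThreshold, minRun = as.integer(minRun),
    windowMb = windowMb, estimator = estimator, region = region,
    minLen = minLen, maxDs = maxDs, densityMethod = densityMethod,
    stages = stages)
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Build a pipeline configuration from a YAML file
#'
#' Top-level keys map to [pipelineConfig()] arguments; the \code{simArgs}
#' mapping is forwarded to [simSpec()].
#'
#' @param path YAML config path.
#' @param ... Overrides applied after the file is read.
#' @export
readPipelineConfig <- function(path, ...) {
  y <- yaml::read_yaml(path)
  over <- list(...)
  y[names(over)] <- over
  do.call(pipelineConfig, y)
}

.stageDir <- function(config, stage) {
  d <- file.path(config$outDir, stage)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  d
}

# atomic TSV write: temp file in the same directory, then rename
.writeTsv <- function(df, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  data.table::fwrite(df, tmp, sep = "\t")
  file.rename(tmp, path)
  invisible(path)
}

.writeManifest <- function(dir, stage, config, inputs = character()) {
  man <- list(stage = stage, seed = config$seed,
    parameters = config[setdiff(names(config), c("spec", "outDir"))],
    inputs = as.list(if (length(inputs)) md5sum(inputs) else character()),
    package = as.character(utils::packageVersion("StrataScan")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

.simDir <- function(config) file.path(config$outDir, "simulate")

.readSimPopulation <- function(config, population) {
  d <- .simDir(config)
  f <- file.path(d, sprintf("sites_%s.tsv", population))
  if (!file.exists(f))
    stopf("missing input %s: run the 'simulate' stage first", f)
  samples <- readSampleSheet(file.path(d, "samples.tsv"))
  list(sites = readSiteCounts(f, "tsv"),
    samples = samples[samples$population == population & samples$assay == "dna", ])
}

.stageSimulate <- function(config) {
  d <- .stageDir(config, "simulate")
  spec <- config$spec
  sims <- simulatePopulations(spec)
  allSamples <- list(); truthS <- list(); truthC <- list()
  for (p in names(sims)) {
    .writeTsv(sims[[p]]$sites[, .(scaffold = scaffold_id, pos,
      sample = sample_id, A, C, G, T)], file.path(d, sprintf("sites_%s.tsv", p)))
    allSamples[[p]] <- sims[[p]]$samples
    truthS[[p]] <- sims[[p]]$truth$strata
    truthC[[p]] <- sims[[p]]$truth$expectedCalls
  }
  ex <- simulateExpression(spec)
  orth <- simulateOrthologs(spec)
  .writeTsv(do.call(rbind, c(allSamples, list(ex$samples))), file.path(d, "samples.tsv"))
  .writeTsv(spec@genes, file.path(d, "genes.tsv"))
  writeGenomeLayout(spec@layout, file.path(d, "layout.tsv"))
  .writeTsv(do.call(rbind, truthS), file.path(d, "truth_strata.tsv"))
  .writeTsv(do.call(rbind, truthC), file.path(d, "truth_calls.tsv"))
  .writeTsv(data.frame(gene_id = rownames(ex$counts), ex$counts,
    check.names = FALSE), file.path(d, "expression_counts.tsv"))
  .writeTsv(ex$truth, file.path(d, "expression_truth.tsv"))
  .writeTsv(orth, file.path(d, "orthologs.tsv"))
  .writeManifest(d, "simulate", config)
  invisible(d)
}

.stageCoverage <- function(config) {
  d <- .stageDir(config, "coverage")
  lab <- .readSimPopulation(config, "lab")
  layout <- readGenomeLayout(file.path(.simDir(config), "layout.tsv"))
  cs <- coverageScan(lab$sites, lab$samples, layout, config$window,
    config$reps, config$alpha, config$seed, config$pseudocount, config$minRun)
  .writeTsv(cs$contrast, file.path(d, "scaffold_coverage.tsv"))
  writeTrack(cs$track, file.path(d, "track_coverage.tsv"))
  .writeTsv(.callsToDf(cs$calls), file.path(d, "strata_coverage.tsv"))
  .writeManifest(d, "coverage", config,
    file.path(.simDir(config), "sites_lab.tsv"))
  invisible(d)
}

.callsToDf <- function(gr) {
  data.frame(chromosome = as.character(seqnames(gr)), start = start(gr),
    end = end(gr), evidence = mcols(gr)$evidence,
    nWindows = mcols(gr)$nWindows)
}

.stageSnpDensity <- function(config) {
  d <- .stageDir(config, "snpdensity")
  simDir <- .simDir(config)
  layout <- readGenomeLayout(file.path(simDir, "layout.tsv"))
  genes <- as.data.frame(data.table::fread(file.path(simDir, "genes.tsv")))
  pops <- config$spec@populations$name
  sims <- setNames(lapply(pops, function(p) .readSimPopulation(config, p)), pops)
  gs <- snpGeneStats(sims, genes, layout, config$minCov, config$minorFrac,
    config$pseudocount, config$densityMethod)
  .writeTsv(gs$geneStats, file.path(d, "gene_stats.tsv"))
  writeLines(gs$rivers, file.path(d, "rivers.txt"))
  .writeManifest(d, "snpdensity", config,
    file.path(simDir, sprintf("sites_%s.tsv", pops)))
  invisible(d)
}

.stageExpression <- function(config) {
  d <- .stageDir(config, "expression")
  simDir <- .simDir(config)
  cnt <- as.data.frame(data.table::fread(file.path(simDir, "expression_counts.tsv")))
  counts <- as.matrix(cnt[, -1L, drop = FALSE])
  rownames(counts) <- cnt$gene_id
  genes <- as.data.frame(data.table::fread(file.path(simDir, "genes.tsv")))
  samples <- readSampleSheet(file.path(simDir, "samples.tsv"))
  lens <- setNames(genes$exonicLength, genes$gene_id)
  mat <- rpkm(counts, lens)
  keep <- expressionFilter(mat, samples, config$fpkmThreshold)
  summ <- expressionSummary(mat[keep, , drop = FALSE], samples,
    config$pseudocount)
  .writeTsv(summ, file.path(d, "expression_summary.tsv"))
  .writeManifest(d, "expression", config,
    file.path(simDir, "expression_counts.tsv"))
  invisible(d)
}

.stageScan <- function(config) {
  d <- .stageDir(config, "scan")
  simDir <- .simDir(config)
  layout <- readGenomeLayout(file.path(simDir, "layout.tsv"))
  gsPath <- file.path(config$outDir, "snpdensity", "gene_stats.tsv")
  if (!file.exists(gsPath))
    stopf("missing input %s: run the 'snpdensity' stage first", gsPath)
  geneStats <- as.data.frame(data.table::fread(gsPath))
  ss <- snpScan(geneStats, layout, config$window, config$reps, config$alpha,
    config$seed, config$minRun)
  writeTrack(ss$track, file.path(d, "track_snp.tsv"))
  .writeTsv(.callsToDf(ss$calls), file.path(d, "strata_snp.tsv"))
  .writeManifest(d, "scan", config, gsPath)
  invisible(d)
}

.stageConverge <- function(config) {
  d <- .stageDir(config, "converge")
  simDir <- .simDir(config)
  layout <- readGenomeLayout(file.path(simDir, "layout.tsv"))
  gsPath <- file.path(config$outDir, "snpdensity", "gene_stats.tsv")
  if (!file.exists(gsPath))
    stopf("missing input %s: run the 'snpdensity' stage first", gsPath)
  geneStats <- as.data.frame(data.table::fread(gsPath))
  rivers <- readLines(file.path(config$outDir, "snpdensity", "rivers.txt"))
  res <- convergencePermutation(geneStats, layout, rivers, config$region,
    config$windowMb, config$reps, config$alpha, config$seed,
    estimator = config$estimator, bandWindow = config$window)
  out <- list(region = list(chromosome = res@chromosome, start = res@start,
      end = res@end),
    per_river_p = as.list(res@perRiverP),
    region_qualifies = res@regionQualifies,
    n_windows_sampled = res@nSampled, n_windows_qualifying = res@nQualifying,
    n_redraws = res@nRedraws, empirical_p = res@empiricalP,
    band_upper = res@bandUpper, seed = res@seed)
  jsonlite::write_json(out, file.path(d, "convergence.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .writeManifest(d, "converge", config, gsPath)
  invisible(d)
}

.stageFasterx <- function(config) {
  d <- .stageDir(config, "fasterx")
  orthPath <- file.path(.simDir(config), "orthologs.tsv")
  if (!file.exists(orthPath))
    stopf("missing input %s: run the 'simulate' stage first", orthPath)
  rows <- filterOrthologs(readOrthologTable(orthPath), config$minLen,
    config$maxDs)
  agg <- aggregateDivergence(rows)
  cis <- do.call(rbind, lapply(unique(rows$category), function(cat)
    data.frame(category = cat,
      bootstrapCIDivergence(rows, cat, config$reps, config$alpha,
        deriveSeed(config$seed, "ci", cat)))))
  xCats <- setdiff(unique(rows$category), "autosome")
  tests <- list()
  for (cat in xCats) {
    tests[[cat]] <- list(
      omega_one_tailed = categoryPermutationTest(rows, cat, "autosome",
        "omega", config$reps, "one_tailed_a_greater", config$seed)$p,
      dN_two_tailed = categoryPermutationTest(rows, cat, "autosome", "dN",
        config$reps, "two_tailed", config$seed)$p,
      dS_two_tailed = categoryPermutationTest(rows, cat, "autosome", "dS",
        config$reps, "two_tailed", config$seed)$p)
  }
  .writeTsv(agg, file.path(d, "divergence.tsv"))
  .writeTsv(cis, file.path(d, "divergence_ci.tsv"))
  jsonlite::write_json(tests, file.path(d, "fasterx_tests.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .writeManifest(d, "fasterx", config, orthPath)
  invisible(d)
}

.STAGES <- c("simulate", "coverage", "snpdensity", "expression", "scan",
  "converge", "fasterx")

#' Run one pipeline stage
#'
#' Each stage reads its inputs from earlier stages' output directories
#' under \code{config$outDir}, writes its outputs atomically, and drops a
#' machine-readable manifest (parameters, seed, input checksums, package
#' version) alongside them.
#'
#' @param name One of simulate, coverage, snpdensity, expression, scan,
#'   converge, fasterx.
#' @param config A [pipelineConfig()].
#' @return The stage output directory, invisibly.
#' @export
runStage <- function(name, config) {
  if (!inherits(config, "PipelineConfig")) stopf("config must come from pipelineConfig()")
  if (length(name) != 1L || !name %in% .STAGES)
    stopf("unknown stage '%s'; valid stages: %s", name,
      paste(.STAGES, collapse = ", "))
  msgf("[%s] running", name)
  switch(name,
    simulate = .stageSimulate(config),
    coverage = .stageCoverage(config),
    snpdensity = .stageSnpDensity(config),
    expression = .stageExpression(config),
    scan = .stageScan(config),
    converge = .stageConverge(config),
    fasterx = .stageFasterx(config))
}

# boundary recovery: max |called - true| over matched intervals, bp
.boundaryError <- function(callsDf, truthDf, evidence) {
  tr <- truthDf[truthDf$evidence == evidence, , drop = FALSE]
  ca <- callsDf[callsDf$evidence == evidence, , drop = FALSE]
  if (!nrow(tr)) return(NULL)
  vapply(seq_len(nrow(tr)), function(i) {
    if (!nrow(ca)) return(Inf)
    # match the call with the largest overlap with this truth interval
    ov <- pmin(ca$end, tr$end[i]) - pmax(ca$start, tr$start[i])
    j <- which.max(ov)
    if (ov[j] <= 0) return(Inf)
    max(abs(ca$start[j] - tr$start[i]), abs(ca$end[j] - tr$end[i]))
  }, numeric(1))
}

#' Run the full pipeline and aggregate a report
#'
#' Executes the enabled stages in dependency order, then writes
#' \code{report.json} summarizing stratum calls (with boundary-recovery
#' errors against the simulation truth), the convergence result, the
#' Faster-X divergence table, and the expression summary. Stages disabled
#' in \code{config$stages} are skipped and marked absent in the report.
#'
#' @param config A [pipelineConfig()].
#' @return The report, invisibly (also written as JSON).
#' @export
runAll <- function(config) {
  for (s in intersect(.STAGES, config$stages)) runStage(s, config)
  report <- list(seed = config$seed)
  simDir <- .simDir(config)
  truth <- if (file.exists(file.path(simDir, "truth_calls.tsv")))
    as.data.frame(data.table::fread(file.path(simDir, "truth_calls.tsv"))) else NULL
  windowSpanBp <- function(trackPath) {
    if (!file.exists(trackPath)) return(NA_real_)
    tr <- readTrack(trackPath)
    if (!nrow(tr)) return(NA_real_)
    median(tr$end - tr$start)
  }
  covCallsPath <- file.path(config$outDir, "coverage", "strata_coverage.tsv")
  if (file.exists(covCallsPath) && !is.null(truth)) {
    calls <- as.data.frame(data.table::fread(covCallsPath))
    labTruth <- truth[truth$population == "lab", , drop = FALSE]
    report$coverage <- list(calls = calls,
      boundary_error_bp = .boundaryError(calls, labTruth, "coverage_deficit"),
      window_span_bp = windowSpanBp(
        file.path(config$outDir, "coverage", "track_coverage.tsv")))
  }
  snpCallsPath <- file.path(config$outDir, "scan", "strata_snp.tsv")
  if (file.exists(snpCallsPath) && !is.null(truth)) {
    calls <- as.data.frame(data.table::fread(snpCallsPath))
    labTruth <- truth[truth$population == "lab", , drop = FALSE]
    report$snp <- list(calls = calls,
      boundary_error_bp = .boundaryError(calls, labTruth, "snp_excess"),
      window_span_bp = windowSpanBp(
        file.path(config$outDir, "scan", "track_snp.tsv")))
  }
  convPath <- file.path(config$outDir, "converge", "convergence.json")
  report$convergence <- if (file.exists(convPath))
    jsonlite::read_json(convPath, simplifyVector = TRUE) else "absent"
  fxPath <- file.path(config$outDir, "fasterx", "divergence.tsv")
  if (file.exists(fxPath)) {
    report$fasterx <- list(
      divergence = as.data.frame(data.table::fread(fxPath)),
      tests = jsonlite::read_json(
        file.path(config$outDir, "fasterx", "fasterx_tests.json"),
        simplifyVector = TRUE))
  } else report$fasterx <- "absent"
  exPath <- file.path(config$outDir, "expression", "expression_summary.tsv")
  if (file.exists(exPath)) {
    summ <- as.data.frame(data.table::fread(exPath))
    trPath <- file.path(simDir, "expression_truth.tsv")
    if (file.exists(trPath)) {
      tru <- as.data.frame(data.table::fread(trPath))
      m <- match(summ$gene_id, tru$gene_id)
      fit <- lm(summ$log2MF ~ tru$trueLog2MF[m])
      report$expression <- list(n_genes = nrow(summ),
        slope_vs_truth = unname(coef(fit)[2L]))
    } else report$expression <- list(n_genes = nrow(summ))
  } else report$expression <- "absent"
  jsonlite::write_json(report, file.path(config$outDir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
  invisible(report)
}
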