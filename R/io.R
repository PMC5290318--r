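# Readers/writers for the plain-text interchange formats and the
# scaffold-to-chromosome assignment rule.
#
# Internal coordinates are 1-based inclusive (pileup convention); BED-like
# track output is 0-based half-open.

.BASES <- c("A", "C", "G", "T")

#' Read per-site allele-count profiles
#'
#' Reads one A/C/G/T count per (site, sample), either from a simple TSV
#' (columns \code{scaffold}, \code{pos}, \code{sample}, \code{A}, \code{C},
#' \code{G}, \code{T}) or from samtools text pileup (one sample per file;
#' read-base symbols are decoded against the reference base, indels,
#' read start/end marks and skips are ignored). Sites absent from the file
#' are treated as not sequenced.
#'
#' @param path Input file.
#' @param format \code{"tsv"} or \code{"mpileup"}.
#' @param sample_id Sample name to attach to mpileup records (one sample per
#'   pileup file).
#' @return data.table with columns \code{scaffold_id}, \code{pos},
#'   \code{sample_id}, \code{A}, \code{C}, \code{G}, \code{T},
#'   \code{coverage}.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("scaffold\tpos\tsample\tA\tC\tG\tT",
#'              "scaf1\t100\tM1\t5\t5\t0\t0"), tf)
#' readSiteCounts(tf)
#' @export
readSiteCounts <- function(path, format = c("tsv", "mpileup"),
                           sample_id = "sample1") {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("file not found: %s", path)
  dt <- if (format == "tsv") .readCountsTsv(path) else .readMpileup(path, sample_id)
  if (nrow(dt) == 0L) warnf("no sites read from %s", path)
  dt[, coverage := A + C + G + T]
  data.table::setkey(dt, scaffold_id, pos, sample_id)
  dt[]
}

.readCountsTsv <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t",
    colClasses = list(character = c(1L, 3L)))
  need <- c("scaffold", "pos", "sample", "A", "C", "G", "T")
  if (!all(need %in% names(dt)))
    stopf("site-count TSV must have columns %s", paste(need, collapse = ", "))
  if (nrow(dt) == 0L) {
    dt <- data.table::data.table(scaffold = character(), pos = integer(),
      sample = character(), A = integer(), C = integer(), G = integer(),
      T = integer())
  }
  for (b in .BASES) {
    v <- dt[[b]]
    if (!is.numeric(v) || anyNA(v))
      stopf("malformed count in column %s (first bad line %d)", b,
        which(!is.finite(suppressWarnings(as.numeric(v))))[1L])
    if (any(v < 0)) stopf("negative count in column %s (line %d)", b, which(v < 0)[1L])
  }
  if (any(dt$pos < 1L)) stopf("positions must be >= 1 (line %d)", which(dt$pos < 1L)[1L])
  data.table::setnames(dt, c("scaffold", "sample"), c("scaffold_id", "sample_id"))
  dt[, c("scaffold_id", "pos", "sample_id", .BASES), with = FALSE]
}

# decode one pileup read-base string into A/C/G/T counts
.decodePileupBases <- function(bases, ref) {
  counts <- c(A = 0L, C = 0L, G = 0L, T = 0L)
  ref <- toupper(ref)
  ch <- strsplit(bases, "", fixed = TRUE)[[1L]]
  i <- 1L
  n <- length(ch)
  while (i <= n) {
    c0 <- ch[i]
    if (c0 == "^") {
      i <- i + 2L            # caret + mapping-quality character
    } else if (c0 %in% c("+", "-")) {
      j <- i + 1L
      while (j <= n && grepl("[0-9]", ch[j])) j <- j + 1L
      len <- as.integer(paste(ch[(i + 1L):(j - 1L)], collapse = ""))
      i <- j + len           # skip the inserted/deleted sequence
    } else {
      if (c0 %in% c(".", ",")) {
        if (ref %in% .BASES) counts[ref] <- counts[ref] + 1L
      } else {
        up <- toupper(c0)
        if (up %in% .BASES) counts[up] <- counts[up] + 1L
        # $, *, >, <, N and quality placeholders contribute nothing
      }
      i <- i + 1L
    }
  }
  counts
}

.readMpileup <- function(path, sample_id) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(data.table::data.table(scaffold_id = character(), pos = integer(),
      sample_id = character(), A = integer(), C = integer(), G = integer(),
      T = integer()))
  recs <- vector("list", length(lines))
  for (k in seq_along(lines)) {
    f <- strsplit(lines[k], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 5L) stopf("malformed mpileup line %d: fewer than 5 fields", k)
    pos <- suppressWarnings(as.integer(f[2L]))
    if (is.na(pos) || pos < 1L) stopf("malformed mpileup line %d: bad position", k)
    cnt <- .decodePileupBases(f[5L], f[3L])
    recs[[k]] <- data.table::data.table(scaffold_id = f[1L], pos = pos,
      sample_id = sample_id, A = cnt[["A"]], C = cnt[["C"]], G = cnt[["G"]],
      T = cnt[["T"]])
  }
  data.table::rbindlist(recs)
}

#' Write site counts as the TSV dialect readSiteCounts() accepts
#'
#' @param sites data.frame/data.table of site counts.
#' @param path Output path.
#' @export
writeSiteCounts <- function(sites, path) {
  dt <- data.table::as.data.table(sites)
  out <- dt[, .(scaffold = scaffold_id, pos, sample = sample_id, A, C, G, T)]
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Read a sample sheet
#'
#' TSV with columns \code{sample_id}, \code{sex} (male/female),
#' \code{population}, \code{assay} (dna/rna).
#' @param path Input TSV.
#' @return data.frame of sample metadata.
#' @export
readSampleSheet <- function(path) {
  df <- as.data.frame(data.table::fread(path, header = TRUE, sep = "\t"))
  need <- c("sample_id", "sex", "population", "assay")
  if (!all(need %in% names(df)))
    stopf("sample sheet must have columns %s", paste(need, collapse = ", "))
  if (anyDuplicated(df$sample_id)) stopf("duplicate sample_id in sample sheet")
  if (!all(df$sex %in% c("male", "female"))) stopf("sex must be male or female")
  if (any(!nzchar(df$population))) stopf("population must be non-empty")
  df
}

#' Read gene models from a BED6+ table
#'
#' BED columns chrom (scaffold), start, end, name (gene id), score, strand,
#' plus an extra \code{exonic_length} column. BED input is 0-based half-open;
#' the returned table uses 1-based inclusive coordinates.
#'
#' @param path Input BED-like TSV (with header).
#' @return data.frame with \code{gene_id}, \code{scaffold_id}, \code{start},
#'   \code{end}, \code{strand}, \code{exonicLength}.
#' @export
readGeneTable <- function(path) {
  df <- as.data.frame(data.table::fread(path, header = TRUE, sep = "\t"))
  need <- c("chrom", "start", "end", "name", "score", "strand", "exonic_length")
  if (!all(need %in% names(df)))
    stopf("gene table must have columns %s", paste(need, collapse = ", "))
  out <- data.frame(gene_id = df$name, scaffold_id = df$chrom,
    start = df$start + 1L, end = df$end, strand = df$strand,
    exonicLength = df$exonic_length)
  if (any(out$start > out$end)) stopf("gene with start > end")
  if (any(out$exonicLength < 1L)) stopf("exonicLength must be >= 1")
  out
}

#' Assign scaffolds to chromosomes by gene majority
#'
#' A scaffold is assigned to the reference chromosome that holds at least
#' \code{threshold} (default 70\%) of its mapped genes, and is discarded
#' otherwise. Assigned scaffolds are ordered along the chromosome by the
#' median reference start position of their genes. Every gene carries
#' exactly one (already resolved) top hit.
#'
#' @param geneHits data.frame with columns \code{gene_id},
#'   \code{scaffold_id}, \code{ref_chromosome}, \code{ref_start}.
#' @param threshold Majority fraction in (0.5, 1]; ties are impossible
#'   above 0.5.
#' @param scaffoldLengths Optional named vector of scaffold lengths (bp);
#'   when absent, a scaffold's span on the chromosome is taken from the
#'   range of its genes' reference starts.
#' @param sexChromosome Optional chromosome id to flag as the sex chromosome.
#' @return A [GenomeLayout-class]; attribute \code{"discarded"} lists
#'   scaffolds that failed the majority rule.
#' @examples
#' hits <- data.frame(gene_id = paste0("g", 1:10),
#'   scaffold_id = "scaf1",
#'   ref_chromosome = rep(c("chr12", "chr3"), c(7, 3)),
#'   ref_start = 1e6 * (1:10))
#' assignScaffolds(hits)   # 7/10 on chr12 -> assigned to chr12
#' @export
assignScaffolds <- function(geneHits, threshold = 0.70,
                            scaffoldLengths = NULL, sexChromosome = NA) {
  if (is.null(geneHits) || nrow(geneHits) == 0L) stopf("empty gene-hit table")
  if (!is.numeric(threshold) || threshold <= 0.5 || threshold > 1)
    stopf("threshold must lie in (0.5, 1]")
  need <- c("gene_id", "scaffold_id", "ref_chromosome", "ref_start")
  if (!all(need %in% names(geneHits)))
    stopf("geneHits must have columns %s", paste(need, collapse = ", "))
  if (anyDuplicated(geneHits$gene_id))
    stopf("each gene must have exactly one hit")

  hits <- geneHits[order(geneHits$scaffold_id, geneHits$gene_id), , drop = FALSE]
  assigned <- lapply(split(hits, hits$scaffold_id), function(d) {
    tab <- table(d$ref_chromosome)
    frac <- tab / nrow(d)
    if (max(frac) >= threshold) {
      chrom <- names(frac)[which.max(frac)]
      on <- d[d$ref_chromosome == chrom, , drop = FALSE]
      data.frame(scaffold_id = d$scaffold_id[1L], chromosome = chrom,
        medStart = median(on$ref_start),
        span = max(1, diff(range(on$ref_start)) + 1))
    } else NULL
  })
  discarded <- names(assigned)[vapply(assigned, is.null, logical(1))]
  asn <- do.call(rbind, assigned[!vapply(assigned, is.null, logical(1))])
  if (is.null(asn) || nrow(asn) == 0L)
    stopf("no scaffold reached the %.0f%% majority threshold", 100 * threshold)

  if (!is.null(scaffoldLengths)) {
    hit <- match(asn$scaffold_id, names(scaffoldLengths))
    asn$span <- ifelse(is.na(hit), asn$span, scaffoldLengths[hit])
  }
  # deterministic: order by median gene start, ties by scaffold id
  asn <- asn[order(asn$chromosome, asn$medStart, asn$scaffold_id), , drop = FALSE]
  pieces <- lapply(split(asn, asn$chromosome), function(d) {
    ends <- cumsum(d$span)
    data.frame(scaffold_id = d$scaffold_id, chromosome = d$chromosome,
      chromStart = c(1, head(ends, -1) + 1), chromEnd = ends)
  })
  sc <- do.call(rbind, pieces)
  rownames(sc) <- NULL
  chroms <- vapply(split(sc$chromEnd, sc$chromosome), max, numeric(1))
  ch <- data.frame(id = names(chroms), length = unname(chroms),
    isSex = names(chroms) %in% sexChromosome)
  layout <- GenomeLayout(ch, sc)
  attr(layout, "discarded") <- discarded
  layout
}

#' Write a window track as BED-like TSV
#'
#' One row per window: \code{chrom}, \code{start}, \code{end} (0-based
#' half-open span from the first to the last unit in the window),
#' \code{value}, \code{ci_low}, \code{ci_high}, \code{significant}.
#'
#' @param track A [WindowTrack-class].
#' @param path Output path.
#' @export
writeTrack <- function(track, path) {
  stopifnot(is(track, "WindowTrack"))
  validObject(track)
  if (is.unsorted(track@unitPos)) stopf("track positions must be sorted")
  n <- length(track@values)
  w <- track@window
  idx <- seq_len(n)
  df <- data.frame(
    chrom = rep(track@chromosome, n),
    start = if (n) track@unitPos[idx] - 1 else numeric(),
    end = if (n) track@unitPos[idx + w - 1L] else numeric(),
    value = track@values,
    ci_low = rep(track@ciLow, n), ci_high = rep(track@ciHigh, n),
    significant = track@significant)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Read a BED-like window track TSV written by writeTrack()
#' @param path Input path.
#' @return data.frame of the track rows.
#' @export
readTrack <- function(path) {
  as.data.frame(data.table::fread(path, header = TRUE, sep = "\t"))
}

#' Serialize / deserialize a GenomeLayout as TSV
#'
#' One row per scaffold with the chromosome metadata repeated, so a single
#' flat file round-trips the object.
#' @param layout A [GenomeLayout-class].
#' @param path File path.
#' @export
writeGenomeLayout <- function(layout, path) {
  sc <- layout@scaffolds
  ch <- layout@chromosomes
  m <- match(sc$chromosome, ch$id)
  df <- data.frame(sc, chromLength = ch$length[m], isSex = ch$isSex[m])
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' @rdname writeGenomeLayout
#' @export
readGenomeLayout <- function(path) {
  df <- as.data.frame(data.table::fread(path, header = TRUE, sep = "\t"))
  ch <- unique(df[, c("chromosome", "chromLength", "isSex")])
  GenomeLayout(
    data.frame(id = ch$chromosome, length = ch$chromLength, isSex = ch$isSex),
    df[, c("scaffold_id", "chromosome", "chromStart", "chromEnd")])
}

#' Locate genes on chromosomes through a GenomeLayout
#'
#' Adds chromosome id and chromosome-scale midpoint position to a gene
#' table; genes on scaffolds absent from the layout (discarded by the
#' majority rule) are dropped, which removes them from all downstream
#' per-gene tables.
#'
#' @param genes Gene table from [readGeneTable()] (scaffold coordinates).
#' @param layout A [GenomeLayout-class].
#' @return Gene table with added \code{chromosome} and \code{position} (bp).
#' @export
locateGenes <- function(genes, layout) {
  sc <- layout@scaffolds
  m <- match(genes$scaffold_id, sc$scaffold_id)
  keep <- !is.na(m)
  if (!all(keep))
    msgf("locateGenes: dropping %d genes on unassigned scaffolds", sum(!keep))
  g <- genes[keep, , drop = FALSE]
  m <- m[keep]
  g$chromosome <- sc$chromosome[m]
  g$position <- sc$chromStart[m] + (g$start + g$end) / 2 - 1
  g
}
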