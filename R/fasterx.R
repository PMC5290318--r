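# Category-level divergence aggregation and permutation/bootstrap inference
# for the Faster-X contrast.

#' Filter ortholog rows for divergence analysis
#'
#' Drops rows whose gap/mask-stripped alignment is shorter than
#' \code{minLen} bp or whose branch dS exceeds \code{maxDs} (mutational
#' saturation). Both comparisons are strict, so boundary values (exactly
#' 300 bp, exactly dS = 2) are retained. Exclusion counts are reported.
#'
#' @param rows Ortholog table with columns \code{aln_len} and
#'   \code{branch_dS} (see [simulateOrthologs()] / [readOrthologTable()]).
#' @param minLen Minimum alignment length (default 300).
#' @param maxDs Maximum branch dS (default 2).
#' @return The retained rows.
#' @export
filterOrthologs <- function(rows, minLen = 300, maxDs = 2) {
  shortAln <- rows$aln_len < minLen
  satDs <- rows$branch_dS > maxDs
  msgf("filterOrthologs: %d short-alignment and %d saturated rows excluded (%d kept)",
    sum(shortAln), sum(satDs & !shortAln), sum(!shortAln & !satDs))
  rows[!shortAln & !satDs, , drop = FALSE]
}

.aggOne <- function(rows) {
  dN <- sum(rows$DN) / sum(rows$N)
  dS <- sum(rows$DS) / sum(rows$S)
  data.frame(n_genes = nrow(rows), dN = dN, dS = dS,
    omega = if (sum(rows$DS) > 0) dN / dS else NA_real_)
}

#' Aggregate substitution counts into category-level divergence
#'
#' Sum-then-divide estimator: dN = sum(DN)/sum(N), dS = sum(DS)/sum(S),
#' omega = dN/dS; never the mean of per-gene ratios, which would let short
#' or low-dS genes dominate. With sum(DS) = 0 omega is undefined (NA, with
#' a warning).
#'
#' @param rows Ortholog table with columns \code{category}, \code{DN},
#'   \code{DS}, \code{N}, \code{S}.
#' @param category Optional single category to aggregate; default is all
#'   categories present.
#' @return data.frame with one row per category: \code{category},
#'   \code{n_genes}, \code{dN}, \code{dS}, \code{omega}.
#' @examples
#' rows <- data.frame(category = "autosome", DN = c(2, 4), DS = c(1, 1),
#'                    N = c(100, 300), S = c(50, 50))
#' aggregateDivergence(rows)$dN  # 6/400 = 0.015
#' @export
aggregateDivergence <- function(rows, category = NULL) {
  if (!is.null(category)) {
    rows <- rows[rows$category %in% category, , drop = FALSE]
    if (!nrow(rows)) stopf("no rows in category '%s'", category)
  }
  if (!nrow(rows)) stopf("empty ortholog table")
  if (any(rows$N <= 0) || any(rows$S <= 0)) stopf("site counts N, S must be positive")
  out <- do.call(rbind, lapply(split(rows, rows$category), .aggOne))
  out <- data.frame(category = rownames(out), out, row.names = NULL)
  if (anyNA(out$omega)) warnf("omega undefined for a category with sum(DS) = 0")
  out
}

.catStat <- function(rows, statistic) {
  switch(statistic,
    dN = sum(rows$DN) / sum(rows$N),
    dS = sum(rows$DS) / sum(rows$S),
    omega = (sum(rows$DN) / sum(rows$N)) / (sum(rows$DS) / sum(rows$S)))
}

#' Permutation test for a divergence contrast between two categories
#'
#' The observed statistic is stat(catA) - stat(catB) under the
#' sum-then-divide aggregation. Category labels are permuted among the
#' pooled rows (group sizes preserved) \code{reps} times. The add-one
#' estimator P = (hits + 1) / (reps + 1) avoids zero P at finite reps.
#' One-tailed tests ask whether catA exceeds catB (the Faster-X direction
#' for omega); dN and dS contrasts are conventionally two-tailed.
#'
#' @param rows Filtered ortholog table.
#' @param catA,catB The two categories to contrast.
#' @param statistic "omega", "dN" or "dS".
#' @param reps Permutation replicates (default 1000).
#' @param tail "one_tailed_a_greater" or "two_tailed".
#' @param seed RNG seed.
#' @return list with \code{observed} (delta), \code{p}, \code{reps}.
#' @export
categoryPermutationTest <- function(rows, catA, catB,
                                    statistic = c("omega", "dN", "dS"),
                                    reps = 1000L,
                                    tail = c("one_tailed_a_greater", "two_tailed"),
                                    seed = 1L) {
  statistic <- match.arg(statistic)
  tail <- match.arg(tail)
  if (reps < 1L) stopf("reps must be >= 1")
  a <- rows[rows$category == catA, , drop = FALSE]
  b <- rows[rows$category == catB, , drop = FALSE]
  if (!nrow(a) || !nrow(b)) stopf("both categories must be non-empty")
  pool <- rbind(a, b)
  nA <- nrow(a)
  obs <- .catStat(a, statistic) - .catStat(b, statistic)
  DN <- pool$DN; DS <- pool$DS; N <- pool$N; S <- pool$S
  perm <- withSeed(deriveSeed(seed, "perm", catA, catB, statistic),
    vapply(seq_len(reps), function(i) {
      idx <- sample.int(nrow(pool), nA)
      sa <- switch(statistic,
        dN = sum(DN[idx]) / sum(N[idx]),
        dS = sum(DS[idx]) / sum(S[idx]),
        omega = (sum(DN[idx]) / sum(N[idx])) / (sum(DS[idx]) / sum(S[idx])))
      sb <- switch(statistic,
        dN = sum(DN[-idx]) / sum(N[-idx]),
        dS = sum(DS[-idx]) / sum(S[-idx]),
        omega = (sum(DN[-idx]) / sum(N[-idx])) / (sum(DS[-idx]) / sum(S[-idx])))
      sa - sb
    }, numeric(1)))
  hits <- if (tail == "two_tailed") sum(abs(perm) >= abs(obs))
          else sum(perm >= obs)
  list(observed = obs, p = (hits + 1) / (reps + 1), reps = reps)
}

#' Bootstrap confidence intervals for category divergence
#'
#' Resamples rows with replacement within the category and returns the
#' percentile interval of each sum-then-divide statistic.
#'
#' @param rows Filtered ortholog table.
#' @param category Category to bootstrap.
#' @param reps Bootstrap replicates (default 1000).
#' @param alpha Two-sided tail probability (default 0.05).
#' @param seed RNG seed.
#' @return data.frame with rows dN, dS, omega and columns \code{estimate},
#'   \code{ci_low}, \code{ci_high}.
#' @export
bootstrapCIDivergence <- function(rows, category, reps = 1000L, alpha = 0.05,
                                  seed = 1L) {
  d <- rows[rows$category == category, , drop = FALSE]
  if (!nrow(d)) stopf("no rows in category '%s'", category)
  DN <- d$DN; DS <- d$DS; N <- d$N; S <- d$S
  n <- nrow(d)
  boot <- withSeed(deriveSeed(seed, "boot", category),
    vapply(seq_len(reps), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      dn <- sum(DN[idx]) / sum(N[idx])
      ds <- sum(DS[idx]) / sum(S[idx])
      c(dn, ds, if (ds > 0) dn / ds else NA_real_)
    }, numeric(3)))
  est <- c(.catStat(d, "dN"), .catStat(d, "dS"), .catStat(d, "omega"))
  qs <- apply(boot, 1L, quantile, probs = c(alpha / 2, 1 - alpha / 2),
    na.rm = TRUE)
  data.frame(statistic = c("dN", "dS", "omega"), estimate = est,
    ci_low = qs[1L, ], ci_high = qs[2L, ], row.names = NULL)
}

#' Read an ortholog divergence table
#'
#' TSV with columns \code{gene_id}, \code{category}, \code{N}, \code{S},
#' \code{branch_dS}, \code{aln_len}, and either raw substitution counts
#' (\code{DN}, \code{DS}) or per-site rates (\code{dN}, \code{dS}) from
#' which counts are reconstructed as rate x sites.
#'
#' @param path Input TSV.
#' @return data.frame of ortholog rows with DN/DS counts.
#' @export
readOrthologTable <- function(path) {
  df <- as.data.frame(data.table::fread(path, header = TRUE, sep = "\t"))
  need <- c("gene_id", "category", "N", "S", "branch_dS", "aln_len")
  if (!all(need %in% names(df)))
    stopf("ortholog table must have columns %s", paste(need, collapse = ", "))
  if (!all(c("DN", "DS") %in% names(df))) {
    if (!all(c("dN", "dS") %in% names(df)))
      stopf("ortholog table needs DN/DS counts or dN/dS rates")
    df$DN <- df$dN * df$N
    df$DS <- df$dS * df$S
  }
  if (any(df$N <= 0) || any(df$S <= 0)) stopf("site counts must be positive")
  if (any(df$DN < 0) || any(df$DS < 0)) stopf("substitution counts must be non-negative")
  df
}
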