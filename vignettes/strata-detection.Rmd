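---
title: "Detecting nascent sex-chromosome strata from male/female resequencing summaries"
author: "StrataScan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting nascent sex-chromosome strata}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(StrataScan)
```

## The inference problem

When recombination between an X and a Y chromosome stops, the Y begins to
diverge in layers ("strata"): regions that stopped recombining longer ago are
more diverged than regions that stopped recently. On a young system the
signal is subtle and layered, and two complementary sex contrasts, both
computed from ordinary resequencing data, separate the layers:

* **Coverage deficit.** Once Y-derived reads are diverged enough to fail to
  map against an X-derived (female) assembly, male read depth on affected
  X scaffolds drops relative to female depth. For each scaffold we compute
  mean depth over sequenced sites per individual, average within sex, and
  form the contrast `log2(male + 1) − log2(female + 1)`. An old stratum
  appears as a run of windows below the autosomal confidence band.

* **Male SNP excess.** Earlier in divergence, Y reads still map but carry
  fixed X–Y differences, so males — the heterogametic sex — show elevated
  *apparent* heterozygosity. Per individual and gene, SNP density is the
  fraction of coverage-filtered genic sites called polymorphic; the same
  pseudocounted log2 M:F contrast turns a young stratum into a run of
  windows above the band, without any accompanying coverage deficit.

Both statistics are scanned with a moving average along scaffolds (coverage)
or genes (SNP density), 40 units per window with step 1 and no partial
windows. The null band is estimated by resampling 40 autosomal units without
replacement 1,000 times and taking the empirical 2.5% and 97.5% percentiles
of the replicate means — one flat band per statistic, describing the null
distribution of a window mean under autosomal exchangeability. Maximal runs
of at least `minRun` consecutive significant windows on the informative side
become stratum calls, spanning from the first unit of the first window to
the last unit of the last window.

## SNP calling and normalization rules

A site is retained when its coverage is at least `minCov = 10` reads;
retained sites enter both the SNP count and the denominator. A retained site
is called a SNP when the second-most-frequent allele count reaches
`minorFrac = 0.3` of the site coverage. The published description of this
rule ("major allele frequency of 0.3 times the site coverage") is ambiguous;
the minor-count reading is the only one under which polymorphic sites are
detectable at all, so that is what the package implements, with the
threshold exposed as a parameter.

The +1 pseudocount is applied to the value being logged — mean coverage,
per-gene density, mean RPKM — even though densities live in [0, 1]. This
makes the density contrast numerically small (approximately
`(dM − dF)/ln 2` for small densities) but keeps the procedure exactly the
published one; the autosomal band is estimated on the same scale, so
inference is unaffected.

For cross-population comparison, per-gene log2 values of each population and
sex are normalized by subtracting the median of that population's
X-chromosome values (the normalized X median is exactly zero); wild-male
values are then expressed relative to the normalized lab-female reference on
the shared gene set. This removes depth and diversity differences between
populations while preserving within-chromosome structure. The lab female is
the natural reference because she carries two X chromosomes and no Y-derived
signal.

## The convergence test

Replicate rivers, each with an upstream and a downstream population, ask
whether X–Y divergence expanded convergently. Per river, a one-tailed
Wilcoxon rank-sum test compares upstream vs downstream per-gene normalized
M:F SNP densities on the focal X region. The genome-wide control asks how
often a random autosomal window of the same physical size (default 10 Mb)
would pass the full qualification: all rivers' one-tailed P below 0.05
*and* the window's median lab M:F density above the upper edge of the
autosomal 95% band. The empirical P is the qualifying fraction over 1,000
sampled windows.

Three decisions the published description leaves open are fixed here as
follows. Windows are genomic spans containing whatever genes fall inside
(not gene-count-matched sets); a chromosome is chosen with probability
proportional to its valid start span, and the start is uniform within it,
so no window overhangs a chromosome end. Windows with fewer than two usable
genes for any river are redrawn and the redraw count reported. The band
used for the lab-median criterion is the same flat scan band (resample size
= the scan window), since the published analysis references a single
"autosomal 95% confidence interval". The plain estimator `qualifying/reps`
matches a report of the "P < 0.004"-style bound; the add-one estimator
`(q+1)/(reps+1)` is available for conservatism.

The Wilcoxon test itself enumerates the exact distribution when the pooled
sample is at most 16 and tie-free, and otherwise uses the normal
approximation with midrank ties and continuity correction (delegated to
`stats::wilcox.test`).

## Faster-X divergence

Orthologs are filtered by strict bounds: gap/mask-stripped alignment length
below 300 bp, or branch dS above 2 (mutational saturation), are excluded;
boundary values are retained. Category-level divergence is sum-then-divide —
`dN = ΣDN/ΣN`, `dS = ΣDS/ΣS`, `ω = dN/dS` — never a mean of per-gene ratios,
which would let short genes and near-zero dS dominate. Contrasts between
genomic categories are tested by permuting category labels among the pooled
rows with group sizes preserved (1,000 replicates; one-tailed for the
Faster-X ω prediction, two-tailed for dN and dS), with the add-one P
estimator so finite replication never reports zero. Label permutation is
the standard reading of a between-category permutation test; gene
resampling is the role of the bootstrap, which provides percentile
confidence intervals within categories. Per-gene substitution counts may be
supplied directly (DN, DS) or reconstructed from per-site rates times site
counts.

## What the generator emulates

`simSpec()` parameterizes a synthetic study whose defaults are the design
this package targets: one outbred laboratory population with four
individuals of each sex, and three rivers each with four upstream and four
downstream males. The genome is three 30-Mb autosomes plus a 26-Mb sex
chromosome, tiled by 20-kb scaffolds (the short-read draft-assembly scale at
which these scans are run), one gene per scaffold, 100 profiled sites per
gene.

* **Coverage** is negative-binomial with mean `depth = 20` and size
  `dispersion = 5` (variance μ + μ²/size; large size recovers Poisson).
  Real short-read depth is overdispersed, which is why the band is estimated
  empirically rather than assumed Poisson.
* **Y-read loss** applies only to the Y-derived half of a male's reads, so
  the male mean inside a stratum is `depth × (1 − δ/2)`; with the default
  δ = 0.5 the expected M:F depth ratio is 0.75 and the expected pseudocounted
  contrast is `log2(20×0.75 + 1) − log2(21) ≈ −0.392` at 20×.
* **Fixed X–Y differences** are drawn once per population at per-site rate
  ρ within a stratum and shared across its males, as fixed differences are.
  At such a site a male read is Y-derived with probability
  `(1 − δ)/(2 − δ)`, so allele counts split binomially around 1/2 when the
  Y still maps fully and around 1/3 at δ = 0.5. Females never carry X–Y
  heterozygosity; male X-hemizygosity outside the pseudoautosomal region is
  therefore modeled implicitly. Baseline heterozygosity π = 0.001 applies
  everywhere in both sexes.
* **Effect sizes.** The published evidence fixes only the signs of the
  stratum effects, not magnitudes; δ = 0.5 and ρ = 0.02 are the package's
  choices. ρ is calibrated as a per-gene fixed-difference load: with 100
  profiled sites per gene it yields about two fixed differences per gene in
  a diverged stratum, which is what full genic profiles of a ~1%-diverged
  region would show, and is the quantity the per-gene density statistic
  responds to. The old stratum (22–25 Mb) carries both δ and ρ; the young
  stratum (ending at 22 Mb) carries ρ only. Upstream populations extend the
  young stratum further (7 Mb vs 4 Mb) and double ρ, emulating convergent
  expansion of the non-recombining region.
* **Expression** is log-normal true RPKM, scaled so expected totals match a
  20-M-read library; a fraction of stratum genes receive a ±2 log2 shift in
  males; counts are Poisson. The truth table records each gene's true
  pseudocounted log2 M:F, so estimates regress on truth with slope 1 at
  high depth. Gene count follows the layout (one gene per scaffold) rather
  than a separate knob, so expression and SNP statistics always refer to the
  same gene models.
* **Orthologs**: per gene DN ~ Poisson(dN·N), DS ~ Poisson(dS·S), with 500
  genes per category, N = 450, S = 150, dS = 0.1 everywhere and ω = 0.225 on
  the X categories vs 0.15 on autosomes (a 1.5-fold Faster-X effect).

Truth tables (effective stratum intervals, expected coverage contrasts,
expected call intervals per evidence class) are emitted alongside each
dataset, so recovery can be scored without reopening generator internals.
Every draw comes from a stream keyed by `deriveSeed(seed, population,
individual)`, so adding a population never perturbs another's data and a
single master seed determines every output byte.

What the generator does *not* emulate: read-level error and mapping bias,
linkage between sites, shared polymorphism between populations
(coalescent structure), recombination gradients, and TMM-style
compositional normalization (RPKM here uses raw library sizes; the
published pipeline's trimmed-mean normalization is out of scope, a
documented divergence). Passing recovery tests therefore demonstrates that
the inference chain is correct under its own assumptions, not that those
assumptions exhaust real data.

## Numerical and scale choices

* Internal coordinates are 1-based inclusive (pileup convention); BED-like
  track output is 0-based half-open.
* The moving average is computed as the literal per-window arithmetic mean,
  so it agrees bit-for-bit with its definition; at scan sizes (hundreds to
  thousands of units) the O(n·w) cost is negligible.
* Scaffold orientation within the assembly is not modeled: scaffolds are
  placed by the median reference-start of their genes, which is sufficient
  at scaffold resolution for window statistics. Genes mapping to multiple
  scaffolds must be resolved upstream (highest-score hit); the assignment
  rule then requires at least 70% of a scaffold's genes on one chromosome.
* `minRun = 5` consecutive significant windows declare a stratum call. With
  overlapping windows (step 1), neighbouring window means share `w − 1`
  units and are strongly autocorrelated, so chance runs of significant
  windows occur and call boundaries blur by up to about one window span;
  calls should be read at window resolution, and isolated short runs
  treated as noise. A hidden-Markov segmentation would sharpen boundaries
  but is deliberately out of scope.
* Sampling without replacement for the band means the replicate mean's
  variance carries a finite-population correction; with autosomal pools an
  order of magnitude larger than the window this is a ~1% effect.
* Problem sizes in the tests are the package's own validation design: unit
  and property tests run on 1–8 Mb toy genomes; recovery and convergence
  checks run on the full default design (116 Mb, seven populations); the
  type-I scan check averages six replicate null genomes at 20 sites per
  gene.

## Known limitations

Stratum calls inherit the resolution of the windowed scan; boundaries are
accurate to roughly one window span, and evidence classes are called
per-statistic rather than jointly. The SNP-density contrast assumes
male-only divergence signal on the X — systems with Z/W inheritance need the
sexes swapped. The convergence test treats rivers as independent replicates;
shared drainage history would inflate its significance and is not modeled.
The per-gene density uses the mean of per-individual densities by default
(pooled counts are available via `densityMethod = "pooled"`), which weights
individuals equally regardless of their filtered-site counts.
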