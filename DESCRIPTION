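Package: StrataScan
Title: Detection and Comparison of Nascent Sex-Chromosome Strata from
    Male and Female Resequencing Summaries
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Infers recently evolved sex-chromosome strata from
    male/female resequencing summaries. Computes per-scaffold read-depth
    and per-gene SNP-density sex contrasts from allele-count profiles,
    scans ordered scaffolds and genes with sliding-window moving averages
    against autosomal bootstrap confidence bands, calls candidate strata
    from runs of significant windows, tests replicate population pairs
    for convergent X-Y divergence with a genomic-window permutation
    scheme, and aggregates per-ortholog substitution counts into
    category-level dN/dS for Faster-X inference. Includes a fully
    parameterized synthetic-data generator (negative-binomial coverage,
    fixed X-Y differences, replicate populations, expression and
    ortholog tables) with serialized ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
biocViews: Genetics, Coverage, SNP, Software
RoxygenNote: 7.3.3
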