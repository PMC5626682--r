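Package: intgen
Title: Integrative Tumor Versus Normal-Cell Transcriptomic and Genomic Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical machinery for integrative tumor-versus-normal
    transcriptomic and genomic studies of the insulinoma/beta-cell type:
    gene- and exon-level differential expression with a Simes-combined
    differential-usage statistic, signed co-expression module detection
    with eigengene-based module-membership p-values and hub ranking,
    Fisher-exact projection of gene signatures onto modules with a capped
    FDR-score transform, a differential-expression-ranked gene axis with
    sliding-window histone-mark smoothing, allele-specific expression
    testing against an empirical reference-bias null via a quasi-binomial
    dispersion correction, and somatic variant burden, recurrence and
    copy-number recurrence summaries. A synthetic-data module generates
    two-group negative-binomial study bundles with planted truth so every
    stage has a parameter-recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    IRanges,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
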