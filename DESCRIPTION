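Package: mgcnv
Title: Copy-Number Variation Analysis of Plant Metabolic Gene Clusters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Population-scale analysis of copy-number variation (CNV) in plant
    metabolic gene clusters (MGCs). Integrates gene copy-number measurements
    from read-depth (RD), multiplex ligation-dependent probe amplification
    (MLPA) and droplet digital PCR (ddPCR) platforms into REF/LOSS/GAIN
    genotype calls with a concordance report; classifies per-accession cluster
    CNV patterns (including the named thalianol-cluster variants); detects
    cryptic divergent gene duplications from excess heterozygous SNP calls in
    inbred genomes; filters and deduplicates inversion calls with a
    two-iteration 50% reciprocal-overlap procedure; pairs terpene-synthase and
    cytochrome P450 genes by genomic proximity and compares paired versus
    nonpaired CNV variability; and provides the rank-based group-comparison
    statistics used throughout (Wilcoxon with continuity correction,
    Kruskal-Wallis with Dunn's post hoc test and Benjamini-Hochberg
    correction, Pearson correlation, and a many-variable phenotype scan).
    A synthetic-cohort generator with planted ground truth makes the entire
    pipeline testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    GenomicRanges,
    IRanges,
    rtracklayer,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
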