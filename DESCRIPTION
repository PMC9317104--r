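Package: mbsmap
Title: Mapping-by-Sequencing of Pooled F2 Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Locates trait-associated genomic intervals from whole-genome
    sequencing of phenotypic-extreme F2 pools (bulk segregant analysis /
    mapping-by-sequencing). Builds a parent-contrasting "gold standard" SNV
    whitelist, computes delta allele frequencies between pools, calls
    variants with significantly differential allele-specific read counts
    (dARCs) by Fisher's exact test with multiple-testing correction,
    clusters dARCs into candidate intervals with spread and gap rules,
    detects zero-coverage regions and gene-level presence-absence
    variations from pool coverage, and reports candidate genes and
    high-impact variants. Includes a seeded F2 cross simulator (Haldane
    recombination, phenotype-tail pool selection, binomial read sampling
    at Poisson depth, engineered deletions) so the whole pipeline is
    testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
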