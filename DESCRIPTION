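Package: methylTE
Title: Whole-Genome Bisulfite Methylome Comparison for Transposable-Element-Rich Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for comparing DNA methylomes of two
    genotypes (e.g. wild type versus a chromatin-remodeler mutant) from
    whole-genome bisulfite sequencing. Implements three-letter converted-genome
    read alignment, per-cytosine methylation calling in CG, CHG and CHH
    contexts, 50-bp windowed fractional methylation, a signed
    percent-methylation-change statistic, matched CG/CHG window comparison,
    transposable-element meta-profiles with an element-inclusion rule,
    chromatin-feature quantile stratification, and TE/gene differential
    expression with family-level RPM summaries. A synthetic-data module
    generates moss-like TE-rich genomes, ground-truth methylomes, bisulfite
    reads and expression counts so that every stage can be validated against
    known truth without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    data.table,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
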