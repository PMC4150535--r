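Package: snipscan
Title: Artificial-Imputation Association Testing for GWAS
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Conditional single-SNP association testing designed to recover
    signal at poorly tagged causal variants. For every genotyped "anchor" SNP
    a nearby "partner" SNP is selected from a local window using a
    simulation-derived correlation-score metric, and the anchor is then tested
    conditional on the partner with a one-degree-of-freedom likelihood-ratio
    test (binary traits) or F test (quantitative traits). Includes a PLINK 1
    binary reader/writer, the full metric-construction simulation, synthetic
    case/control generators driven by three-SNP haplotype-frequency models,
    and a power/type-I-error evaluation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
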