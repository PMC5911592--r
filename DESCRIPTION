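Package: ptvburden
Title: Germline Gene-Panel Variant Classification and Carrier-Burden Statistics
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Rule-based classification of germline variants from multi-gene
    breast cancer predisposition panels and gene-level carrier-burden
    case-control statistics. Implements protein-truncating-variant (PTV)
    calling with nonsense-mediated-decay escape logic (last exon / last 55
    coding bases of the penultimate exon, with functional-domain rescue),
    allele-frequency based benign assignment, IARC five-tier classes,
    per-variant overrides, and consensus damaging-missense flagging; then
    aggregates per-gene carrier counts and compares cases against multiple
    control cohorts and phenotype strata (bilateral disease, receptor status,
    triple-negative phenotype, age at first diagnosis) with Wald odds ratios
    and confidence intervals, Fisher exact tests and Student t tests. A
    synthetic-cohort generator with a known truth table makes the whole
    pipeline testable without access to patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Biostrings,
    rtracklayer,
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
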