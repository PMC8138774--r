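Package: consensomeR
Title: Discovery-Rate Consensome Meta-Analysis and Cross-Species
    Differential Expression Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for case-control transcriptomic meta-analysis built around
    the "consensome": a ranking of genes by the frequency with which they are
    significantly differentially expressed across independent case-control
    datasets, with an exact Poisson-binomial significance model and
    Benjamini-Hochberg false-discovery-rate control. Includes two-group
    differential statistics (Student and Welch t-tests on log-transformed
    normalized abundances, fold changes), confidence-transcript extraction,
    orthology-mapped comparison of human and mouse responses within chimeric
    liver designs (including the human:mouse relative-expression gene set),
    hypergeometric gene-set over-representation with odds ratios, node
    high-confidence-transcriptional-target (HCT) intersection analysis, a
    synthetic-data generator that emulates the statistical structure of
    multi-dataset case-control studies, and a deterministic end-to-end
    pipeline with hashed output manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    tools,
    utils
Suggests:
    fgsea,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
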