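Package: priorfdr
Title: Prior-Informed False Discovery Rate Control for Genome-Wide
    Association Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Multiple-testing procedures for genome-wide association
    studies that exploit prior biological knowledge: whole-genome
    Benjamini-Hochberg adjustment, weighted FDR control with binary
    mean-one weights, and prioritized subset analysis (separate BH
    control within a prioritized and a non-prioritized SNP subset).
    Includes a self-contained case-control GWAS simulator with
    linkage-disequilibrium block structure and a multiplicative
    genotypic-relative-risk disease model, per-SNP association and
    Hardy-Weinberg tests, and a Monte-Carlo evaluation harness for
    realized FDR and locus-level power.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
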