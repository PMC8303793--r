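Package: mrweb
Title: Two-Sample Mendelian Randomization with Causal-Web Confounder
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for two-sample Mendelian randomization from GWAS
    summary statistics: allele harmonization (strand correction, palindromic
    SNP removal, greedy LD clumping), causal-effect estimation via the Wald
    ratio, fixed- and random-effects inverse-variance-weighted (IVW)
    meta-analysis, MR-Egger regression, weighted/simple median and mode-based
    estimators, sensitivity diagnostics (Cochran's Q heterogeneity,
    leave-one-out, Steiger directionality), Benjamini-Hochberg FDR screening
    across many exposure/outcome studies, and classification of third traits
    into confounder, intermediate, reverse-intermediate and collider roles on
    a weighted directed causal graph. Includes a summary-statistics simulator
    with known ground truth (instrument strengths, pleiotropy, LD blocks,
    palindromic and strand-flipped allele codings, planted trait networks) so
    every stage is testable without external GWAS downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
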