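Package: ifishtrial
Title: Immuno-FISH Heterogeneity and Phase II Trial Correlative Analysis
Version: 0.1.0
Authors@R:
    person("TNBC Correlatives", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Correlative and design computations for a single-arm phase II
    JAK1/2-inhibitor study in metastatic triple-negative breast cancer:
    semi-quantitative pSTAT3 immunohistochemistry T-scoring and screening
    funnels, exact operating characteristics of two-stage binomial designs,
    single-cell immuno-FISH image analysis (nucleus segmentation, JAK2/CEP9
    spot counting, pSTAT3 phenotype calling), four-population intratumor
    diversity via Shannon entropy with spatial topology maps and
    immune-infiltrate regression, transcriptional STAT3-pathway
    pharmacodynamics (TPM conversion, gene and signature tests, gene-set
    enrichment), and RECIST-level clinical endpoint summaries. A bundled
    synthetic-data generator produces images, cell tables, expression
    matrices and trial cohorts with known ground truth so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
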