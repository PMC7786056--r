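Package: teastress
Title: Cross-Species Candidate Gene Screening and Stress Expression Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering and profiling cold- and drought-responsive
    candidate genes in tea plant (Camellia sinensis). Implements cross-species
    quartile-rank screening of upregulated genes with ortholog intersection, a
    1-9 combined relevance score (GO annotation, upregulation rank, literature
    evidence), candidate interaction-network assembly from STRING-style edge
    tables with probabilistic-OR channel combination and score thresholding,
    qRT-PCR relative expression by the Livak 2^-ddCq method with per-treatment
    significance and response-category calls, electrolyte-leakage (REC)
    phenotyping with tolerant-genotype selection, and downstream Ward
    clustering, treatment-pair PCA and cross-treatment Pearson correlation
    analysis. A seeded synthetic-data generator with planted ground truth
    emulates the study design for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
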