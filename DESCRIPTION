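Package: dielomix
Title: Joint Diel mRNA-Protein Expression Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for integrating matched transcriptome and proteome time
    courses sampled over a light:dark (diel) cycle. Provides peptide-level
    proteomics filtering, quantile normalization and reference-peptide
    rollup to protein abundances; delay-aware mRNA-protein correlation
    classification with permutation nulls; pathway-level concordance
    scoring of gene-pair set enrichment; consensus co-expression
    clustering; sequence-feature computation (codon adaptation index,
    UTR folding energies, composition); multivariate adaptive regression
    spline models of protein abundance; and residual-quantile detection
    of hypothetically post-transcriptionally regulated genes. A seeded
    synthetic-data generator emulating a four-time-point, replicated
    diel study design makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    limma,
    cluster,
    glmnet,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
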