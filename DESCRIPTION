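Package: targetmap
Title: Drug Target Prediction from Expression Connectivity and
    Compound-Protein Binding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the protein targets through which a drug, herbal
    formula or disease acts, by connectivity mapping of ranked
    differential-expression profiles against a library of target-specific
    gene signatures. Builds per-target consensus signatures from replicate
    perturbation profiles (Spearman-weighted averaging, top/bottom-n gene
    extraction with a decrease-rate size heuristic), scores queries with a
    running-sum effect target score calibrated by permutation (nominal p,
    normalized score, pooled-null false discovery rate), trains a sequence
    based compound-protein binding classifier, classifies targets into
    effect, binding, direct and indirect sets, detects drug-versus-disease
    reversal targets, and maps target sets onto pathways by hypergeometric
    over-representation analysis. Includes a seeded synthetic-data
    generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    pROC,
    stats,
    tools,
    utils
Suggests:
    optparse,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
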