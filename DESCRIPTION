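Package: delvar
Title: Deleterious Missense Variant Classification from Sequence Profiles
    and Structural Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies missense protein variants as deleterious or neutral
    by combining position-specific scoring matrix (PSSM) log-odds features
    with structural-ensemble features derived from Rosetta-style refinement
    score files, in a sparse logistic regression trained with stability-based
    feature selection.  Includes parsers for PSIBLAST ASCII PSSMs, Rosetta
    whitespace score files, PROBE accessibility tables and PDB models;
    native-ensemble normalization of structural score terms; protein-level
    cross-validated ROC/PR evaluation; score-bin enrichment analysis; an
    automated physical interpretation of each deleterious call; and seeded
    synthetic-data generators for every input format.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    glmnet,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
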