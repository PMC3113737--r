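Package: purinesite
Title: Propensity Analysis and Prediction of Adenine and Guanine
    Nucleotide Binding Sites in Proteins
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Structure-based analysis and sequence-based prediction of
    protein binding sites for adenine and guanine phosphates (AMP, ADP,
    ATP, GMP, GDP, GTP and the cyclic monophosphates cAMP and cGMP).
    Reads protein-nucleotide complexes in PDB format, labels binding
    residues by a 4.5 Angstrom any-atom contact rule with a
    main-chain/side-chain by base/phosphate channel decomposition,
    computes per-amino-acid binding propensities with bootstrap error
    bars, encodes residues as 105-dimensional sliding-window PSSM
    feature vectors, trains support vector regression models with
    leave-one-protein-out jackknife evaluation, and builds cross-ligand
    prediction matrices scored by ROC AUC.  Includes a synthetic-fixture
    generator that builds toy complexes with controlled contact geometry
    and toy profiles with a plantable binding signal.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    Biostrings,
    dplyr,
    e1071,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
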