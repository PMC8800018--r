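Package: dockscreen
Title: Ensemble Docking Virtual Screening with Naive Bayesian Consensus Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Multi-conformation (ensemble) structure-based virtual screening:
    binding-site extraction and RMSD clustering of protein conformers with
    representative selection by resolution, per-conformation docking and
    screening power validation (re-dock RMSD, score-distribution t-tests,
    ROC/AUC), a Laplacian-corrected naive Bayesian classifier that combines
    per-conformation docking scores into a consensus score, and the sequential
    hit-triage cascade (rank, Bayesian re-score, Lipinski/Veber and REOS
    drug-likeness filters, Tanimoto/Butina diversity clustering, hot-residue
    interaction filter). Includes geometric protein-ligand interaction
    detection, occupancy and ligand RMSF utilities, and seeded synthetic
    generators for score tables, descriptor tables, fingerprints, toy
    complexes and snapshot series. Docking engines are external; score tables
    are inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    bio3d,
    ChemmineR,
    optparse,
    knitr
Config/testthat/edition: 3
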