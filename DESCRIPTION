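Package: ligscreen
Title: Ligand-Based Virtual Screening with Fingerprint QSAR, Decoy
    Validation and Trajectory Analytics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end toolkit for ligand-based virtual screening
    against a protein target. Ingests bioactivity tables and compound
    libraries, converts IC50 values to pIC50, builds binary molecular
    fingerprint matrices (Morgan and path-based generators, plus
    ingestion of precomputed 881-bit PubChem fingerprint tables),
    performs variance-based descriptor selection and schema
    harmonisation, and fits a deep feed-forward pIC50 regressor with
    L1/L2 regularisation, dropout and Adam optimisation. Screening
    utilities rank library predictions and select the upper quartile;
    drug-likeness filters (Lipinski, Ghose, Veber, Egan, Muegge) prune
    the hits. Retrospective validation against decoy sets provides
    Tanimoto similarity scoring, ROC/AUC, enrichment factors and
    rank-based distribution tests. A trajectory-analytics layer supplies
    Kabsch superposition, RMSD/RMSF/Rg/SASA/hydrogen-bond series,
    essential dynamics (PCA), dynamic cross-correlation matrices and
    MM/GBSA component bookkeeping. Synthetic-data generators with
    planted signal make every stage testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    igraph,
    jsonlite,
    bio3d,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
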