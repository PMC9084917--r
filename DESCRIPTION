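Package: decoyrank
Title: Regression-Based Selection of Near-Native Peptide-MHC Structural Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies near-native structural models (decoys) of nonameric
    peptide/MHC class I complexes. Computes binding-groove-superposed peptide
    RMSDs (Kabsch superposition on heavy-chain residues 1-180), solvent
    accessible surface areas (Shrake-Rupley), and per-residue energetic
    feature matrices; trains ordinary least squares, partial least squares,
    and epsilon-insensitive support vector regression functions that predict
    each decoy's heavy-atom RMSD from its features; and ranks and selects
    decoys by predicted RMSD instead of energy, with rank-correlation,
    selection-comparison and position/amino-acid stratified evaluation.
    Includes a synthetic decoy-ensemble generator with known ground truth so
    the whole pipeline is testable without external modeling software.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
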