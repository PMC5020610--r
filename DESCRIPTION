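Package: dimerscope
Title: Conformational Ensemble Analysis of Peptide Dimers and Aromatic Ligands
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of conformational ensembles of amyloidogenic peptide
    dimers, such as the human islet amyloid polypeptide (hIAPP) dimer, with
    and without small aromatic ligands. Implements Kabsch-Sander
    hydrogen-bond-based secondary-structure assignment with derived
    per-residue profiles and beta-strand run-length distributions, Daura
    (GROMOS-style) clustering on chain-independent main-chain RMSD with
    Kabsch superposition, residue-residue and ligand-residue
    contact-probability maps, two-dimensional free-energy surfaces with
    basin detection, aromatic stacking and cation-pi geometry analysis,
    collision-cross-section estimation by the projection approximation,
    replica-exchange diagnostics, and a synthetic-ensemble generator that
    builds peptide backbones, beta-hairpins, dimers and ligand placements
    with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
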