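Package: pocketsim
Title: Microenvironment-Based Functional Assessment of Predicted Protein Structures
Version: 0.1.0
Authors@R:
    person("Maintainer", "Dev", email = "dev@example.org", role = c("aut", "cre"))
Description: Featurizes spherical physicochemical microenvironments around
    functional-site centers of protein structures (80 properties over six
    concentric shells, 7.5 Angstrom radius), scores site similarity between
    predicted and experimental structures with a Tanimoto-based mutual-best-match
    alignment, computes companion structural quality measures (Kabsch RMSD,
    GDT_TS, TM-score, site-local RMSD), and ranks model ensembles functionally
    versus structurally with z-scores and rank correlations. Includes a
    deterministic synthetic-structure generator producing reference structures
    with concave (optionally ligand-bound) sites and noise-graded decoy
    ensembles for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
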