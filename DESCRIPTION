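Package: rnafrag
Title: RNA Fragment Libraries and Structural-Space Completeness Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds libraries of short continuous RNA fragments (di- to
    penta-nucleotides) from PDB or mmCIF structure files, represents them
    in six reduced atomic reference frames and a 15-atom common heavy-atom
    set, removes conformational redundancy with a three-stage hierarchical
    clustering protocol based on Kabsch superposition RMSD, and quantifies
    how the observed RNA structural space has grown over time. Includes
    pseudo-torsion (eta/theta) analysis with an angle-distance metric,
    RMSD correlations between representations, helix/loop region
    classification from base-pair annotations, and a deterministic
    synthetic-structure generator so every pipeline stage can be exercised
    without downloading coordinates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    tidyr
Config/testthat/edition: 3
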