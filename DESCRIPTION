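Package: capriq
Title: Model Quality Assessment for Predicted Protein Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assessment engine for predicted protein complexes in the CAPRI
    tradition: interface quality metrics (native-contact recall, ligand,
    interface and side-chain RMSD, steric clashes), the four-category CAPRI
    classification and the continuous DockQ score, multi-interface
    assessment-unit aggregation, and predictor-group ranking by CAPRI score,
    summed DockQ and positive-truncated Z-scores. Ships a deterministic
    synthetic-complex generator producing decoy sets with analytically known
    metrics, so the whole pipeline can be exercised end-to-end without any
    external structure data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
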