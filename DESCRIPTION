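Package: faahscreen
Title: Ligand-Based Scaffold Enrichment and Repurposing Screens for FAAH
    Inhibitors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A ligand-based virtual-screening pipeline for fatty acid amide
    hydrolase (FAAH) inhibitor repurposing: activity-data curation into
    inhibitor and property-matched decoy sets, Murcko framework, Bemis-Murcko
    skeleton and plain-ring decomposition with enrichment (P) and potency (I)
    scoring, a flag-discretized logistic activity classifier built on ROC
    cutoffs of 2D and conformer-based 3D descriptors, a composite repurposing
    score (RpS) with ROC thresholding, and a docking-result post-filter based
    on ligand efficiency and binding energy. Includes a synthetic-library
    generator with planted scaffold enrichment so the whole cascade is
    testable without database downloads. Molecule handling is delegated to
    Open Babel via ChemmineR/ChemmineOB.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    igraph,
    tibble,
    dplyr,
    rlang,
    readr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
SystemRequirements: Open Babel (obabel and obminimize on the PATH)
Config/testthat/edition: 3
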