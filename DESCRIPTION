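Package: ribomod
Title: Reading the Modification Landscape of Ribosome Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Geometric annotation of high-resolution ribosome atomic models.
    Parses mmCIF/PDB coordinate files, classifies every residue into chemical
    categories (modified ribonucleotides and amino acids, metals, waters,
    polyamines) via an editable component map, takes a census of modifications
    and their distances to the peptidyl transferase centre, assesses
    pseudouridine plausibility from the hydrogen-bond geometry of the free
    N1-H donor, discriminates Mg2+ from K+ and water by coordination-sphere
    geometry, maps polyamine binding environments including water bridges, and
    traces water-mediated hydrogen-bond networks. Ships a deterministic
    synthetic-structure generator with ground-truth manifests so the whole
    pipeline is testable without downloading any deposited model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tidyselect,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
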