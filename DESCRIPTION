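Package: cybrin
Title: Residue Interaction Networks for Cytonuclear Hybrid Ribosome Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Structure-based screening of plastid-nuclear incompatibility
    candidates in the plastid ribosome. Builds residue interaction networks
    (RIN) from PDB/mmCIF coordinates with an any-atom minimal-distance rule,
    applies lineage-specific amino-acid substitutions to construct all
    plastid-by-nuclear hybrid combination models via template-based side-chain
    rebuilding and clash-driven rotamer selection, classifies plastid-nuclear
    interface contacts (hydrogen bond, salt bridge, hydrophobic, polar),
    computes betweenness, closeness, degree and eigenvector centralities with
    per-network Z-scores, and summarises centrality shifts across combinations
    by principal component analysis with per-residue contributions. Ships a
    synthetic-data generator (toy complexes with planted contact geometry,
    planted lineage alignments, closed-form graph fixtures) and machine-
    readable fixtures of the published interface-interaction and centrality
    tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
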