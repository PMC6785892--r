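Package: epibench
Title: Non-Redundant Benchmark Datasets of Immune Receptor-Epitope Structural Complexes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Curates benchmark datasets of antibody-antigen, TCR-pMHC and
    MHC-ligand 3D complexes. Filters structures on resolution, R-free and
    CDR completeness, computes receptor-antigen interfaces and core-epitopes
    at a 4 Angstrom heavy-atom cutoff, and clusters complexes by antigen
    sequence identity, receptor CDR identity, epitope conformational
    similarity (sorted intra-site distance matching, PMax/PMin scores) and
    MHC G-domain sequence to yield non-redundant receptor-epitope pairs.
    Includes a seeded synthetic-complex generator so the whole pipeline is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
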