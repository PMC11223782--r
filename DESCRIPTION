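Package: pocketome
Title: Interface Pocket Detection, Characterization and Pocketome Graphs for
    Protein Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects cavities at protein-protein and protein-ligand interfaces
    as grid-based negative images, filters structures by experimental quality
    metadata, retains and classifies pockets (orthosteric competitive,
    orthosteric non-competitive, allosteric), computes a 109-entry shape and
    pharmacophore descriptor vector per pocket, measures pocket similarity
    with a Gaussian-kernel Pocket Similarity Index on standardized
    descriptor-space Euclidean distances, and exports the resulting pocketome
    as a minimum spanning tree with annotation columns. Also labels interface
    hot-spot residues from per-residue free-energy-change tables, and ships
    deterministic synthetic fixture generators (groove-plus-peptide
    complexes, descriptor matrices, quality headers) so the whole pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
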