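Package: etrace
Title: Evolutionary Trace Analysis of Paralogous Protein Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the evolutionary trace (ET) workflow for comparing
    paralogous protein families such as the beta-secretases BACE1 and BACE2.
    From a multiple sequence alignment of orthologs spanning two paralog
    groups, the package builds a neighbor-joining tree, cuts it into groups,
    classifies every alignment column as conserved, group-specific or
    neutral, renders the ET sequence, and maps residue statuses onto PDB
    structures. Structural utilities extract ligand-binding sites by a
    distance cutoff, superpose paralog structures over matched C-alpha atoms
    (Kabsch), and annotate binding-site residues with their trace status.
    A synthetic-data generator produces ortholog families with planted
    column statuses and toy protein-ligand complexes with known binding
    sites so that every pipeline stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    bio3d,
    seqinr,
    Biostrings,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
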