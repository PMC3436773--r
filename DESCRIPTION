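Package: motif3d
Title: Constraint-Based Definition and Search of 3D Structural Motifs in Protein Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Defines small, sequentially non-contiguous three-dimensional structural
    motifs as sets of constraints (residue type, secondary structure, inter-atomic
    distance bounds, sequence separation), generates such motif specifications from
    existing PDB-format structures, searches structures for every combination of
    residues satisfying all constraints with early combinatorial pruning, and
    superposes and scores hits by least-squares backbone rmsd.  Includes a synthetic
    structure generator with planted motifs and a brute-force search oracle for
    fully offline testing, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
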