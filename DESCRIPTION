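Package: fraglib
Title: Variable-Length Fragment Library Generation for De Novo Protein
    Structure Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Generates, filters and ranks variable-length backbone fragment
    libraries for fragment-assembly protein structure prediction. Fragments
    of 6 to 20 residues are extracted from a culled template database by a
    combination of random sampling and exhaustive search, scored with an
    environment-specific (Ramachandran-region) substitution score, a
    predicted secondary-structure match score and a predicted torsion-angle
    score, filtered with secondary-structure-class-aware acceptance cutoffs,
    ranked by torsion score, enriched by structural similarity to the
    top-ranked fragment, and complemented with nine-residue fragments mined
    from protein threading hits. Library quality is assessed by precision
    and coverage against the native structure over a grid of RMSD cutoffs,
    computed by optimal Calpha superposition. Includes a synthetic-fixture
    generator (idealized backbones built from canonical torsions plus
    configurable prediction error models) so the full pipeline can be
    exercised without external structure or prediction servers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    Biostrings,
    graphics,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
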