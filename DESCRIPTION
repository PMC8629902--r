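Package: zfmut
Title: Domain-Aware Analysis of Zinc-Finger Somatic Mutations and ZF-DNA Structural Metrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing somatic mutation catalogues of C2H2
    zinc-finger (ZF) transcription factors such as CTCF, together with
    structural metrics for ZF-DNA complexes. Parses HGVS protein and cDNA
    notation, classifies variants, and computes catalogue statistics
    (recurrence, composition, transition/transversion ratios, the 20/20
    tumour-suppressor rule, impact-score comparisons). Detects C2H2/C2HC
    motifs, assigns DNA-binding helix coordinates (-6..+6), computes
    observed/expected domain enrichment and positional mutation frequencies,
    and builds sequence-logo information content in bits. Structure tools
    enumerate protein-DNA contacts (hydrogen bond, electrostatic,
    hydrophobic, cation-pi) from PDB files, tally them per ZF, diff bond
    sets between wild type and mutant, measure ZF-DNA centroid shifts and
    classify folding free-energy changes. Trajectory tools provide Kabsch
    superposition, RMSD series, per-residue RMSF profiles and paired
    nonparametric tests. Seeded synthetic-data generators emulate every
    input so the full pipeline runs and is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
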