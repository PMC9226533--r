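Package: gemdraft
Title: Draft Genome-Scale Metabolic Model Reconstruction and Benchmarking
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A scriptable toolkit for assembling draft genome-scale
    metabolic models (GSMMs) and auditing them against curated references.
    Covers homology-based enzyme annotation with a frequency-plus-taxonomy
    score, de novo draft assembly from an EC-to-reaction catalogue,
    template-based reconstruction via bidirectional best hits with
    gene-protein-reaction (GPR) rule propagation, genome-derived biomass
    equation construction, subcellular-localization integration, topological
    network audits (mass balance, dead ends, blocked reactions), and
    alias-mediated draft-versus-curated comparison with precision, recall,
    TP/FP ratio, F1 and Jaccard-distance metrics. Reads and writes SBML
    level 3 (fbc), GenBank flat files and FASTA.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    xml2,
    yaml,
    jsonlite,
    Biostrings,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
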