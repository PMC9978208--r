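Package: statefold
Title: Conformational-State Biasing of Template-Based Protein Structure
    Prediction for GPCRs and Kinases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for steering template-based protein structure prediction
    toward user-defined conformational states.  Provides an annotation record
    model for state-labelled GPCR and kinase template structures
    (activation state, DFG, alphaC-helix, salt-bridge and activation-loop
    labels), annotation-driven template filtering, ranking, top-k and
    randomized selection, shallow multiple-sequence-alignment subsampling,
    template-region MSA removal and sliding-window masking, an ensemble
    driver with a pluggable predictor contract (including a deterministic
    mock predictor for offline testing), and conformational evaluation of
    model ensembles: Kabsch superposition, segment-restricted C-alpha RMSD
    (transmembrane helices vs loops), pTM-RMSD rank correlation, unfolded
    model filtering and nearest-reference classification of kinase
    conformational features.  A synthetic fixture generator builds toy
    GPCR and kinase conformer libraries, annotation tables and alignments
    so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
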