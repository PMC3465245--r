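Package: dismeta
Title: Consensus and Template-Coverage Meta-Prediction of Protein
    Intrinsic Disorder
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Per-residue prediction of intrinsically disordered protein
    regions by accuracy-weighted consensus over primary predictor scores
    and by coverage of the target sequence in fold-recognition alignments,
    with a genetic-algorithm trained tier-weight model and a combined
    two-channel predictor.  Includes the CASP-style evaluation machinery
    (weighted score Sw, threshold-averaged Sww, Matthews correlation,
    ROC/AUC, bootstrap error estimates, Wilcoxon comparison, residue-level
    cross-validation bins), readers and writers for sequence, label,
    score-profile, hit-table and PDB REMARK 465 formats, and synthetic
    fixture generators of controlled discriminative power for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
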