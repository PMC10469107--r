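Package: withdrawr
Title: Cross-Database Drug Withdrawal Prediction from SMILES
Version: 0.1.0
Authors@R: person("withdrawr", "maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Tools for predicting post-market drug withdrawal from chemical
    structure alone. Harmonizes withdrawn/approved status claims from multiple
    drug databases under an any-source-withdrawn rule, standardizes SMILES
    (canonical structure keys, removal of structureless, single-element and
    over-long entries), builds leave-one-database-out train/test splits in
    agreement and no-agreement modes, trains a from-scratch transformer
    encoder classifier over SMILES tokens (scaled dot-product attention,
    multi-head attention, pre-LayerNorm residual blocks) alongside a
    circular-fingerprint boosted-stumps baseline, and evaluates with ROC AUC,
    PR-AUC, accuracy, specificity, sensitivity, MCC, disagreement-subset
    accuracy and probability-ranking reports. Includes a synthetic multi-source
    corpus generator with a planted toxicophore signal and controlled
    cross-source label conflicts so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
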