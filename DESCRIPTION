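Package: hdxensemble
Title: Ensemble Reweighting and Conformational Population Quantification
    from HDX-MS Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Integrative analysis of hydrogen-deuterium exchange mass
    spectrometry (HDX-MS) data with candidate structural ensembles.
    Predicts peptide-level deuterium uptake from per-residue amide
    contacts and hydrogen bonds via an empirical protection-factor
    model with Bai-Englander intrinsic exchange rates, normalizes
    experimental uptake against a maximally deuterated (MaxD) control,
    tests differential HDX between states with a hybrid
    confidence-interval plus Welch's t-test criterion, fits ensemble
    frame weights to the normalized data by maximum-entropy reweighting
    under an apparent-work budget, and quantifies fractional
    conformational populations with subsampling uncertainty, per-peptide
    RMSE and peptide-exclusion robustness checks. Includes a synthetic
    two-state data generator so the full workflow is testable without
    external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
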