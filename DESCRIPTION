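Package: retfuse
Title: Uncertainty-Aware Ensemble Fusion for Five-Way Retinal Diagnosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for fusing heterogeneous diagnostic submodels (language-model
    ensembles and an optional image classifier) into a single calibrated
    probability distribution over five retinal conditions (no, mild and severe
    diabetic retinopathy, glaucoma, and age-related macular degeneration).
    Implements length-based pseudo-loss confidence scoring, a reciprocal-rank
    fusion baseline, a reliability- and entropy-weighted aggregator with
    missing-modality neutrality, seeded calibration splits with top-1
    reliability estimation, ranking and calibration metrics (top-k accuracy,
    mean reciprocal rank, expected calibration error, Brier score), threshold
    based triage mapping, JSONL input/output, and a synthetic submodel-ensemble
    simulator so the whole pipeline can be exercised without clinical data or
    model API access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
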