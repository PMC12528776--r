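Package: airtree
Title: Airway-Branch Decomposition and Volume Biomarkers from Chest CT Masks
Version: 0.1.0
Authors@R: person("Airtree", "Developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Geometric decomposition of binary airway segmentations from
    volumetric chest CT into trachea, medium, small and terminal branch
    classes using projection distance maps and percentile thresholds, with
    airway volume biomarkers normalised to lung volume (STermAV, SSmallAV,
    SMedAV, STotalAV, SPAV), skeleton-based branch morphometry (generations,
    length, tortuosity, branching angles), and a survival-analysis layer
    (Cox proportional hazards, Kaplan-Meier tertile strata, Harrell's C,
    time-dependent ROC with censoring weights) for prognostic evaluation.
    Includes a synthetic airway-tree phantom generator with ground-truth
    generation labels so every stage is testable without patient data, and
    a minimal NIfTI-1 reader/writer for mask input and output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    survival,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
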