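Package: emdad
Title: Empirical Mode Decomposition EEG Features and Classifier Benchmarks
    for Alzheimer's Staging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A reproducible pipeline for EEG-based clinical decision support
    in Alzheimer's disease: synthetic three-class resting-state EEG cohort
    generation with class-dependent band-power contrasts, elliptic band-pass
    pre-processing, empirical mode decomposition (EMD) of channel epochs into
    intrinsic mode functions, seven per-component scalar features (approximate
    entropy, energy, logarithmic band power, mean frequency, norm,
    peak-to-peak value, zero-crossing rate), six classifier configurations,
    and dual cross-validation (stratified k-fold and subject-grouped
    hold-out) over five diagnostic classification problems, with EDF and
    tabular input/output.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    e1071,
    rpart,
    jsonlite,
    data.table,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    MASS,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
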