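Package: neutrofun
Title: Neutrophil Function Analysis for Pneumonia Cohort Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantitative analysis of neutrophil function assays used in
    community-acquired pneumonia cohort studies: chemotaxis metrics (speed,
    velocity, chemotactic index, displacement, distance, directness) from
    time-lapse cell tracks; extracellular-flux glycolysis kinetics (ECAR to
    proton-efflux-rate conversion, basal glycolysis, PMA fold change, QC
    against oligomycin and 2-deoxyglucose controls) and oxidative-burst
    kinetics (peak OCR, time to peak, total oxygen consumption); flow
    cytometry summaries (annexin V / propidium iodide viability quadrants,
    isotype-gated percent positive, MFI); and a two-group cohort statistics
    harness (Shapiro-Wilk normality gating, t-test / Mann-Whitney / Fisher's
    exact dispatch, normal-approximation sample-size calculation). Seeded
    synthetic-data generators (von Mises biased random-walk tracks, phased
    flux curves, gamma-pulse burst curves, two-group cohorts) emulate the
    study measurements so the whole pipeline is testable without raw data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
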