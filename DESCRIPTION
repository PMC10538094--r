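Package: ncakit
Title: Weighted Calibration, Bioanalytical Validation and Noncompartmental
    Pharmacokinetics for Targeted LC-MS/MS Serum Assays
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the quantitative stage of a targeted LC-MS/MS
    bioanalytical study of an orally dosed small molecule in serum:
    1/x-weighted linear calibration with back-calculation, limit-of-detection
    and limit-of-quantification definitions from signal-to-noise ratios,
    quality-control precision/accuracy and stability acceptance checks,
    per-subject noncompartmental pharmacokinetic analysis (Cmax, Tmax, lag
    time, terminal-phase lambda-z regression with best-fit window selection,
    linear-trapezoidal AUC with tail extrapolation, CL/F and Vd/F), and
    population summaries.  A seeded synthetic-data module simulates
    concentration-time profiles from a one-compartment first-order absorption
    model with lag, log-normal inter-individual variability, proportional
    assay noise and censoring below the lower limit of quantification, plus
    calibration and QC batches with concentration-proportional response
    noise, so the whole pipeline is testable without access to clinical
    samples.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
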