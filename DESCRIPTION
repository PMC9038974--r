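Package: mpiphantom
Title: Digital Twin of a Dynamic Myocardial Perfusion Phantom for SPECT Tracer Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulates a closed-loop myocardial perfusion phantom (well-mixed
    flow circuit with sorbent-based tracer trapping and recirculation filters)
    and the full dynamic-SPECT tracer-kinetic analysis chain around it:
    dynamic frame binning with partial-volume, spillover and Poisson counting
    effects, time-activity-curve post-processing (injected-activity
    normalisation, resampling, spline peak alignment, background subtraction,
    ensemble statistics), and net-retention myocardial blood flow estimation
    with AHA 17-segment territory reporting, so that software-derived MBF can
    be validated against analytic ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    pracma,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
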