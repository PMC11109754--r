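Package: landrisk
Title: Viscoelastic ACL Loading and Lower-Limb Injury-Risk Analysis for
    Single-Leg Landings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for analysing lower-limb injury risk during single-leg
    drop landings. Implements a strain-rate-dependent viscoelastic
    constitutive model of the anterior cruciate ligament in which collagen
    fibres are recruited according to a two-parameter Weibull distribution,
    an EMG-driven second-order recursive muscle-activation model, landing
    biomechanics summary metrics (landing-phase detection, zero-phase
    Butterworth filtering, joint power and energy dissipation, 101-point
    time normalisation), correlation and min-max risk-standardisation
    statistics with risk trade-off (intersection and balanced-range)
    analysis, and a calibrated synthetic cohort generator producing both
    summary tables and trial-level waveforms so the full pipeline can be
    exercised end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    MASS,
    Matrix,
    pracma,
    signal,
    stats
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
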