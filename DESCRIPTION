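Package: hearscreen
Title: Simulation and Diagnostic Accuracy of Picture-Pointing Hearing
    Screening in Preschool Children
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Seeded simulator and analysis toolkit for app-based preschool
    hearing screening with a six-alternative picture-pointing spondee task.
    Provides the adaptive 40-30-20 dB HL descent protocol with a 2-of-3
    pass criterion, a probabilistic child response model (guess, lapse,
    slope, timeout), headphone acoustics (RMS equalization, calibration
    coefficients, passive ambient-noise isolation), a synthetic cohort
    generator with a configurable prevalence structure, a simulated
    conditioned-play-audiometry reference, and the diagnostic-accuracy
    statistics used to validate such screeners: percent agreement, Cohen's
    kappa with a kappa-paradox diagnostic (PABAK), sensitivity and
    specificity with Clopper-Pearson exact confidence intervals, exact
    McNemar comparisons, paired t tests on test durations, and exact
    reconstruction of 2x2 tables from printed summary statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
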