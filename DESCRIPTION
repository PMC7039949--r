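Package: pulseabr
Title: Pulse-Shape Efficiency Analysis for Electrically Evoked Auditory
    Brainstem Responses
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to study the charge efficiency of cochlear-implant
    pulse shapes with electrically evoked auditory brainstem response
    (eABR) recordings. Generates charge-balanced rectangular and ramped
    biphasic stimuli, simulates eABR sweep sets with known ground truth,
    removes stimulus artifacts (linear interpolation and exponential
    trend subtraction), applies zero-phase Butterworth bandpass
    filtering, performs interleaved-delay up-sampling and polarity
    averaging, extracts wave amplitudes, latencies and thresholds, fits
    linear and broken-stick growth functions and strength-duration
    regressions, and implements a lowpass-filter (windowed-RMS)
    threshold-prediction model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
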