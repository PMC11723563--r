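Package: hfoarea
Title: Electrode Surface Area Effects on High-Frequency Oscillation Measurement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of how electrode contact surface area shapes
    the measurement of high-frequency oscillations (HFOs) in intracranial EEG.
    Provides a lumped electrode-tissue measurement model for platinum contacts,
    a generator of synthetic iEEG containing HFO pulse trains over 1/f background
    activity, a two-threshold RMS burst detector with artifact rejection, virtual
    electrode shorting on an 8x8 high-density grid, HFO feature extraction (rate,
    amplitude, duration, peak frequency, spatial spread), and the rank-sum based
    statistical comparisons used to study the size dependence of HFO rate per
    unit electrode area.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    signal,
    stats,
    utils,
    jsonlite,
    yaml,
    data.table
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
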