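Package: stunEEG
Title: EEG and Behavioural Assessment of Controlled-Atmosphere Stunning in Poultry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to assess loss of consciousness and brain death in gas-stunned
    broiler chickens from single-channel electroencephalography (EEG), together
    with behavioural ethogram accounting around loss of posture. Implements
    zero-phase 1-30 Hz band-pass filtering, 1 s epoch Welch spectra (1024-point
    Hamming-windowed FFT, 50 percent overlap, zero frequency removed), per-epoch
    spectral features (total power, median frequency F50, spectral edge F95,
    band contributions), baseline artifact exclusion, and threshold-persistence
    detection rules for loss of consciousness (F50 halving or 65 percent Delta
    increase), spectral brain death (90 percent total-power drop) and the
    isoelectric pattern. Includes a synthetic-data generator for EEG traces,
    ethogram event streams and gas-concentration profiles with known ground
    truth, ethogram summary tables with Pearson chi-squared and Student t
    comparisons, gas-compliance checks, and a reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    signal,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0), withr, knitr, rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
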