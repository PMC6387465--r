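Package: neuroproxy
Title: Non-Cerebral Proxies of EEG Alpha Activity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for comparing cerebral (EEG) and
    non-cerebral (neck and wrist) biopotential recordings under eyes-open and
    eyes-closed conditions. Provides a synthetic cohort generator with
    volume-conducted alpha activity, Butterworth band-pass preprocessing with
    amplitude and trend artifact rejection, Hanning-window power spectral
    density estimation on a 0.25 Hz grid, individual alpha frequency (IAF)
    estimation by peak and gravity methods with IAF-anchored band definitions,
    EEG-to-non-EEG alpha-profile correlation and common-pattern selection,
    a from-scratch stepwise linear discriminant analysis (SWLDA) classifier,
    and repetition-paired cross-validated AUC/accuracy evaluation. Includes
    EDF read/write and BrainVision Core read support.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
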