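Package: pabr
Title: Parallel Auditory Brainstem Response Stimuli and Derived-Band Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for the parallel auditory brainstem response (pABR)
    paradigm: generation of Poisson-timed multi-frequency toneburst stimuli
    with high-pass pink-noise maskers, forward simulation of single-channel
    EEG with a parametric cochlear-place model, response extraction by padded
    frequency-domain cross-correlation with inverse-variance (Bayesian) trial
    weighting, and place-specificity read-outs via octave-wide derived-band
    subtraction, automated wave V latency picking, and a noise-floor-corrected
    response-size statistic.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
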