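Package: stridecycle
Title: Stride-Cycle Analysis of Visual Performance During Walking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing rhythmic modulation of behavioural
    performance over the walking stride cycle. Epochs strides from vertical
    head-position traces, projects target and response events onto
    normalised stride phase, detects oscillations with a swept
    fixed-frequency Fourier model and max-statistic permutation nulls,
    quantifies Bayesian population prevalence (MAP and highest posterior
    density intervals) and phase clustering (Rayleigh test), and simulates
    complete walking-psychophysics sessions - including a QUEST adaptive
    staircase and cumulative-normal psychometric fits - with known
    ground-truth oscillation parameters for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
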