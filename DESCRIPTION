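Package: hrvstress
Title: Heart Rate Variability and Questionnaire Analysis for
    Performance-Stress Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for within-subjects studies of performance stress that
    combine frequency-domain heart rate variability (LF/HF sympatho-vagal
    balance from RR-interval series: median-filter artifact repair, 4 Hz
    cubic-spline tachogram resampling, zero-phase Butterworth band
    decomposition, windowed band power) with questionnaire scoring (STAI
    Form Y1 state anxiety; 19-item simulation evaluation batteries) and the
    matching inference procedures (exact one-sample Wilcoxon signed-rank
    against a scale midpoint, paired t, two-factor fully within-subjects
    ANOVA). A synthetic-data generator produces RR series with known
    spectral ground truth, ectopic-beat corruption, and full multi-
    participant study datasets, so every pipeline stage has a
    parameter-recovery test surface without any recorded human data.
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
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
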