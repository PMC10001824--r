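Package: hrvretest
Title: Test-Retest Reliability Analysis of Short-Term Heart Rate Variability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing the test-retest reliability of short-term
    heart rate variability (HRV) responses to submaximal exercise. Extracts
    the standard time-domain, frequency-domain and nonlinear HRV indices
    (RMSSD, SDNN, mean R-R, HF/LF/VLF band powers, Poincare SD1/SD2,
    Baevsky's stress index, composite autonomic indices) from beat-to-beat
    R-R interval recordings with explicit artifact handling and analysis
    window selection. Describes between-session differences with an
    intercept-only Bayesian model summarised in the SEXIT style (posterior
    median, highest-density interval, probability of direction, region of
    practical equivalence, Savage-Dickey Bayes factor), quantifies
    session-to-session agreement with Bayesian Lin's concordance correlation
    and Bland-Altman limits of agreement, and ships a seeded synthetic
    cohort generator for calibration and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    coda,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), optparse, withr, knitr, rmarkdown
Config/testthat/edition: 3
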