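Package: stepsync
Title: Dyadic Rhythmic Entrainment Analysis for Annotated Step-Onset Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quantifying rhythmic entrainment between two walking
    individuals from annotated footfall onset times. Converts discrete step
    onsets into uniformly sampled pulse series, estimates stepping tempo by
    windowed autocorrelation and between-subject lag by cross-correlation,
    maps onsets to phase angles on a reference period and applies circular
    statistics (Rayleigh test, Watson-Williams ANOVA, Jammalamadaka-Sarma
    correlation with bootstrap intervals), and infers per-bout leadership by
    Granger causality with AIC lag selection in a bivariate vector
    autoregression. Includes a coupled-walker phase-correction simulator for
    fixtures, calibration, and parameter-recovery studies, plus an
    orchestration layer that emits machine- and human-readable reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    signal,
    nortest,
    jsonlite,
    withr,
    stats,
    utils
Suggests:
    lmtest,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
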