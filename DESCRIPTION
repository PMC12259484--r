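Package: risktailor
Title: Behavioural Risk Scoring, Tailored Messaging and
    Confidence-Interval-Based Determinant Relevance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for questionnaire-based behavioural risk assessment and
    computer-tailored intervention design. Implements a three-factor
    behavioural risk engine (exposure, hygiene, uncontrollable factors) over a
    short risk-estimation questionnaire, an acyclic behaviour change diagram
    (ABCD) message-tailoring engine, Confidence Interval-Based Estimation of
    Relevance (CIBER) summaries with two Potential for Change indices for
    ranking intervention targets, and a synthetic-respondent generator with
    planted determinant-behaviour correlations and planned missingness for
    validating the whole pipeline without access to field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ggplot2,
    jsonlite,
    patchwork,
    rlang,
    stats,
    tibble,
    utils
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
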