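Package: pregsignal
Title: Multimodal Pregnancy Signaling Analysis for Primate Field Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting and analyzing multimodal pregnancy signaling
    in wild primates from field data. Implements hormone-based reproductive
    timeline classification (fecal progestogen rise detection, fertile-window
    construction, conception dating against delivery records), receptor-space
    facial color metrics from chart-calibrated photographs, David's Score
    dominance ranking from agonistic interaction records, and a two-part
    (hurdle) mixed-model analysis of behavioral, vocal, color and endocrine
    outcomes with likelihood-ratio model comparison. A synthetic study
    generator reproduces the statistical structure of a focal-sampling field
    study of Japanese macaques so the full pipeline can be exercised and
    validated by simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    readr,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    generics,
    glmmTMB,
    lme4
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
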