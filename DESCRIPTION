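Package: riskgroups
Title: Discovery and Temporal Validation of High-Mortality Subgroups in
    Child Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for discovering and temporally validating subgroups of
    children at elevated mortality risk in health and demographic
    surveillance (HDSS) cohorts. Provides a synthetic cohort generator
    with planted spatial, single-factor and synergistic risk structure;
    inverse probability of censoring weighting for informative emigration;
    Kaplan-Meier and weighted crude risks; a sliding-window spatial risk
    scan with small-cell masking; backdoor-adjusted risk differences from
    weighted linear-probability models with sandwich standard errors; a
    from-scratch targeted maximum likelihood estimator (TMLE) for risk
    differences; a non-negative shallow-network risk decomposition with
    per-feature risk contributions and contribution-profile clustering;
    and an inductive-deductive pipeline that discovers candidate
    subgroups in a hypothesis-generating cohort and re-estimates them,
    with synergy statistics, similarity tests, combined estimates and
    population attributable fractions, in a temporal validation cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    survival,
    sandwich,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
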