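Package: kapeis
Title: Outcome Scoring and Effect Estimation for Pesticide-Safety Cluster Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for two-wave, three-arm cluster-randomized
    pesticide-safety trials among smallholder farmers: knowledge/attitude/
    practice (KAP) questionnaire scoring with reverse-scored Likert items,
    the semi-quantitative Exposure Intensity Score (EIS) with its PPE and
    hygiene sub-components, poisoning-symptom counts, cluster-design sample
    size and design-effect machinery, CONSORT-style flow accounting, and
    baseline-adjusted mixed-effects estimation of intervention effects with
    cluster random intercepts. A synthetic cohort generator emulates the
    trial's data structure (intraclass correlation, baseline-follow-up
    correlation, arm effects, attrition) so the whole pipeline is testable
    at desk scale.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    lme4,
    lmerTest,
    ggplot2,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
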