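Package: pcscore
Title: Polyconnectomic Scoring of Functional Connectomes Against Disorder Templates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes polyconnectomic scores (PCS), the weighted average of an
    individual's resting-state functional connectivity over the non-zero edges
    of a disorder-specific connectome-summary-statistic (CSS) template, and the
    statistical pipeline built around them: template contribution summaries at
    the edge and network level, family-clustered linear mixed-effects
    association and moderation models with conditional slopes and delta-R2,
    longitudinal change-score analyses, and a synthetic twin-family cohort
    generator with planted stress-by-vulnerability effects for end-to-end
    validation without access to restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    lme4,
    readr,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
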