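Package: convoload
Title: Conversational Multitasking and Clinician Workload from EHR Event Logs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures conversational multitasking in clinician secure
    messaging and relates it to electronic health record (EHR) workload.
    Builds active-conversation intervals from messaging metadata, computes
    per-minute concurrency traces and exposure categories, derives EHR
    active time and patient-chart switching from audit logs, assembles
    clinician-day cohorts under activity and shift rules, and fits linear
    mixed-effects models with crossed random intercepts for clinician and
    clinical service. Includes a synthetic generator of messaging metadata
    and audit logs with planted effect sizes so the whole pipeline is
    testable end to end, including parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    readr,
    rlang,
    lme4,
    lmerTest,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
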