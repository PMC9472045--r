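Package: natkit
Title: Semiautomated Chart-Review Toolkit for Phenotyping Cognitive Status in Electronic Health Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for semiautomated electronic-health-record (EHR) chart review
    aimed at phenotyping cognitive status (cognitively normal, cognitively
    impaired, or undetermined). Provides a flat-file chart-bundle data model with
    study-period filtering and note segmentation, regex lexicon matching and
    highlighting for cognition and activities-of-daily-living keywords,
    structured-data feature engineering (dementia medications and ICD code
    families, relevant laboratory panels, utilization counts), pluggable note
    triage and CI-first ranking, rule-based label suggestion with annotation
    session bookkeeping, an evaluation-statistics layer (Cohen kappa, exact
    paired Wilcoxon signed-rank timing comparisons, learning-effect and
    demographic summaries), a seeded synthetic-EHR cohort generator with planted
    ground truth, and static HTML dashboard/patient reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    e1071,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
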