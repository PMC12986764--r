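Package: ranovol
Title: Volumetric Response Assessment in Neuro-Oncology and Landmark
    Survival Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Implements volumetric adaptations of the RANO, mRANO and
    RANO 2.0 response-assessment criteria for newly diagnosed
    glioblastoma as per-scan state machines over longitudinal
    contrast-enhancing and T2/FLAIR lesion volumes: baseline selection
    (post-operative versus post-radiotherapy), progression and response
    thresholds, pseudoprogression confirmation logic inside and beyond
    the 12-week post-radiotherapy guard, and dated progression calls
    including re-resection and bevacizumab overrides.  Derives
    progression-free, post-progression and overall survival per
    criterion, and provides the comparative statistical battery:
    Spearman PFS-OS correlation, Kruskal-Wallis with Dunn/Bonferroni
    post-hoc tests, Mann-Whitney U, and fixed-landmark Cox
    proportional-hazards models.  A synthetic cohort generator emulates
    the clinical structure of a standard-of-care glioblastoma cohort so
    the full pipeline is testable end to end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    survival,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
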