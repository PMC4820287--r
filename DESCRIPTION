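Package: aaapheno
Title: Rule-Based ePhenotyping of Abdominal Aortic Aneurysm Cases and
    Controls from Coded EHR Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A portable implementation of a deterministic electronic health
    record (EHR) phenotyping algorithm for abdominal aortic aneurysm (AAA).
    Subjects in a coded-EHR extract (ICD-9 diagnosis events and CPT procedure
    events) are classified as AAA cases (Type 1: repair procedure; Type 2:
    ruptured-AAA specialty encounter; Type 3: two or more specialty-clinic AAA
    diagnosis dates), controls, or excluded with a stated reason (phenocopy,
    age bounds, early onset, unconfirmed AAA code, no recent encounter). The
    package also provides blinded chart-review sampling, positive predictive
    value (PPV) with exact Clopper-Pearson confidence intervals, multi-site
    pooled validation reports, and a synthetic coded-encounter generator with
    per-subject ground truth so the whole pipeline can be exercised and
    validated without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    readr,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
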