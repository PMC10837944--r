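Package: akicomorbid
Title: Acute Kidney Injury Comorbidity Mining from ICU Creatinine, Urine
    Output and Diagnosis Streams
Version: 0.1.0
Authors@R:
    person("AKI", "Comorbid Team", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects and stages acute kidney injury (AKI) from serum
    creatinine and urine-output time series using the KDIGO consensus
    criteria, normalises ICD-9/ICD-10 diagnosis codes into per-patient
    category itemsets, mines AKI-disease comorbidity pairs with the
    Apriori algorithm scored by support, kulczynski and lift, verifies
    mined pairs against reference datasets with a category-to-subcategory
    fallback re-mining algorithm, and derives AKI-centred disease
    networks, stage-3 risk factors and organ-crosstalk scores. A
    synthetic-cohort generator with planted associations of known lift
    makes the whole pipeline testable without access to credentialed
    clinical databases.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    Matrix,
    igraph,
    jsonlite,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
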