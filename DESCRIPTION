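Package: TMIstrat
Title: Blood Tumour Mutation Index Stratification for NSCLC Survival Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Constructs circulating tumour DNA (ctDNA) biomarkers for
    stratifying non-small cell lung cancer patients treated with docetaxel
    or atezolizumab: mutation-class burden scores (bTMB, sbTMB), a per-gene
    survival-screened unfavourable mutation score (UMS), exhaustive
    log-rank-minimising single and dual (U-shaped) biomarker cut-offs, and
    a composite tumour mutation index (TMI) fitted on a discovery cohort
    and applied frozen to validation cohorts. Ships a seeded synthetic
    cohort simulator with planted cut-off, U-shape and unfavourable-gene
    effects so every stage is testable without trial data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    survival,
    pROC,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
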