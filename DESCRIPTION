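Package: cllcea
Title: Cost-Effectiveness Modelling of Genomic Testing-Guided Treatment in
    Chronic Lymphocytic Leukaemia
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Markov cohort decision-analytic model comparing five test-treatment
    strategies for 'go-go' patients with chronic lymphocytic leukaemia in the UK
    NHS: genetic (FISH/Sanger) or genomic (targeted NGS) testing used to stratify
    patients between FCR-based chemotherapy and ibrutinib. Implements tunnel-state
    cohort propagation with discounting and half-cycle correction, cost-effectiveness
    and cost-utility evaluation, incremental analysis with strict and extended
    dominance, univariate/scenario/threshold sensitivity analyses, probabilistic
    sensitivity analysis with cost-effectiveness acceptability curves, and a
    societal costing extension (friction-cost productivity losses, informal care,
    out-of-pocket costs). Ships the published per-cycle state costs and utility
    weights as fixtures and a seeded generator of complete, internally consistent
    parameter sets for all remaining model inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
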