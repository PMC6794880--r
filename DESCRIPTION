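Package: painrank
Title: G1 Order-Relation Weighting and TOPSIS Ranking for Treatment Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-criteria decision analysis for clinical treatment selection.
    Derives criterion weights from expert importance orderings and adjacent
    importance ratios (the G1 order-relation method, a simplified Analytic
    Hierarchy Process), aggregates weights across an expert panel, and ranks
    treatment alternatives by relative closeness to the ideal solution (TOPSIS).
    Ships a fully worked case study ranking four interventional therapies for
    chronic cancer pain from a five-expert panel, together with leave-one-out
    and ratio-perturbation rank-stability analyses and synthetic panel and
    score-matrix generators for property testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
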