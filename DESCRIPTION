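Package: arasdm
Title: Entropy-Weighted Additive Ratio Assessment for Multi-Criteria
    Treatment Selection
Version: 1.0.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for ranking treatment alternatives evaluated on mixed
    benefit/cost criteria with the additive ratio assessment (ARAS)
    method. Qualitative assessment tables on bounded ordinal scales are
    converted to numeric decision matrices, criterion weights are derived
    objectively from Shannon entropy of the column score distributions,
    and alternatives are scored by their utility degree relative to an
    ideal optimal alternative. Includes equal-weight and single-criterion
    dominance scenarios for sensitivity analysis, rank-order comparison
    with Kendall's tau, a reproducible synthetic decision-problem
    generator, a bundled case study on provisional restorations in
    single-tooth implant treatment, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
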