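Package: earlymcda
Title: Reflective Multicriteria Decision Analysis for Early Access to Medicines
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for appraising individual early-access medicine requests
    with a reflective multicriteria decision analysis (MCDA) framework of the
    EVIDEM family. Provides criteria framework management (a quantitative
    core model plus a qualitative contextual tool), panel weight elicitation
    and normalization, linear additive value estimates with per-criterion
    value contributions, contextual-tool tallies, test/re-test consistency
    checking with an exact Wilcoxon signed-rank test, and a seeded synthetic
    panel generator so the whole pipeline can be exercised without real
    committee data. Includes a command-line interface for the simulate,
    weigh, score and retest steps.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
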