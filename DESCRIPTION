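Package: seqregraph
Title: Sequences of Regressions and Graphical Markov Models for
    Bone, Body Composition, and Metabolic Factors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fits sequences of regressions over an a-priori block ordering of
    variables and assembles the result into a regression graph (directed
    arrows between boxes, dashed edges within response boxes, full lines
    within context boxes). Provides m-separation and anterior-set machinery
    implementing the global Markov property of regression graphs, a
    linear-Gaussian oracle (implied covariance and partial correlations),
    partition queries, tertile-by-tertile geometric-mean interaction grids,
    and a calibrated synthetic cohort generator for parameter-recovery
    experiments on pQCT bone phenotype, body habitus, and plasma biomarker
    data from postmenopausal women.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
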