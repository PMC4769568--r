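Package: plasmodeDE
Title: Plasmode-Based Benchmarking of Differential Expression Methods for
    Low-Count RNA-Seq Transcripts
Version: 0.1.0
Authors@R:
    person("Plasmode", "Maintainers", email = "maintainers@plasmode.dev",
           role = c("aut", "cre"))
Description: Tools to benchmark negative-binomial differential expression
    (DE) inference on RNA-seq count data with an emphasis on low-count
    transcripts. Provides a synthetic count generator with a realistic
    abundance distribution, null and spiked ("DE") plasmode construction by
    balanced sample repartitioning, two negative-binomial GLM engines (an
    LFC-shrinkage engine and a robust observation-weights engine with a
    tunable prior-degrees-of-freedom dispersion moderation, plus a classic
    unweighted variant), reads-present and CPM filtering rules, abundance
    stratification, Benjamini-Hochberg adjustment, and confusion-matrix
    performance evaluation (FPR, power, precision, NPV, accuracy) aggregated
    across plasmodes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
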