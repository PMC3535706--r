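Package: rnaihits
Title: Hit Selection and Simulation for Drug-Sensitivity RNAi Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Statistical toolkit for high-throughput RNAi screens that look
    for genes modulating sensitivity to a chemotherapeutic drug. Provides a
    fully parameterized simulator of plate-based viability screens (normal
    and gamma-skewed noise), normalization to untreated non-silencing
    controls, four per-siRNA hit-selection statistics (log2 fold change,
    two-sample t, sensitivity index, and a linear model with a drug-by-RNAi
    interaction tested by a 2-df deviance statistic), plus an evaluation
    harness that estimates false-positive and false-negative rates of each
    method over simulated scenario grids.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
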