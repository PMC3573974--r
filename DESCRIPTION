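Package: cyclecheck
Title: Timing-Robust Multi-Valued Boolean Models of the Budding Yeast Cell
    Cycle
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for building, simulating and verifying multi-valued
    threshold Boolean models of the budding yeast cell cycle regulatory
    network.  Supports synchronous and fully asynchronous update semantics,
    explicit-state construction of transition graphs, exhaustive attractor
    and basin-of-attraction analysis, checkpoint-ordering (hazard) property
    checking with replayable counterexamples under a fairness reduction,
    cell-cycle phase segmentation statistics, random edge-mutation
    robustness screening, and export of models to the NuSMV input language.
    Three reference models of the yeast cell cycle network ship as
    code-built fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    igraph,
    jsonlite,
    generics,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
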