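Package: cisnet
Title: Sequence-Explicit Simulation of Gene Regulatory Network Evolution
Version: 0.1.0
Authors@R:
    person("cisnet", "developers", email = "cisnet@example.org", role = c("aut", "cre"))
Description: Simulates the evolution of gene regulatory networks in which
    transcription-factor binding sites live on explicit promoter DNA.
    Per-factor binding landscapes over all 65,536 8-mers translate point
    mutations into quantitative changes of an interaction matrix, which
    drives discrete-time sigmoidal expression dynamics inside a
    population under stabilizing selection. Includes an analysis suite
    for quantifying how mutational robustness evolves: mutation-event
    classification, robustness decomposition, binding-site conservation
    and avoidance, redundancy, and network rewiring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings
Config/testthat/edition: 3
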