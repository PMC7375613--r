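Package: ribopool
Title: Whole-Cell Codon-Resolution Simulation of mRNA Translation with
    Shared Ribosome and tRNA Pools
Version: 0.1.0
Authors@R:
    person("Doron", "Weiss", email = "dweiss@example.org", role = c("aut", "cre"))
Description: A deterministic, timer-driven generalization of the totally
    asymmetric simple exclusion process (TASEP) for simulating translation
    of thousands of mRNA molecules in a single cell that share finite,
    conserved pools of ribosomes and tRNAs. Elongation is resolved at the
    codon level through per-codon state machines, wobble-aware codon-tRNA
    interaction coefficients, and effective supply-demand ratios (ESDR and
    RSDR) that couple waiting times to live resource availability,
    including a tRNA-recycling correction. The package also provides tAI
    and CAI codon indices with coefficient optimization, pool-size and
    initiation-time calibration, heterologous-gene insertion with
    folding-energy-dependent initiation, synonymous-variant generation,
    genome randomization modes, a repeated train/test greedy
    forward-selection regressor with SCR feature prioritization, and a
    synthetic-data generator so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
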