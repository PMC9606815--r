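Package: seqconsol
Title: Cortico-Hippocampal Consolidation of Sequential Memories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulator of systems-level memory consolidation for temporal
    sequences in a coupled cortico-hippocampal network. Items are rate
    neurons with shunting (Grossberg-style) recurrent competitive dynamics
    and slow inactivation currents; directional associations between items
    are learned with a causal rate-based plasticity rule in a fast-learning,
    fast-forgetting hippocampus and a slow-learning, slow-forgetting cortex.
    Slow-wave-sleep nights are simulated as blocks of UP states in which
    items are cued stochastically in proportion to a salience trace (a
    moving average of waking activation, with a null item for silent UP
    states), producing time-compressed replays that consolidate sequence
    memories into cortex. Ships declarative experiment presets (baseline
    consolidation, hippocampal-output lesion, salience-biased replay
    competition, sequence interference, hippocampal learning disabled in
    sleep, overlapping sequences), recall accuracy/recall time metrics,
    replay statistics, and a YAML-configured, seed-reproducible runner.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
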