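Package: larvatax
Title: Run-and-Turn Segmentation and Navigational Statistics for Larval
    Phototaxis Trajectories
Version: 0.1.0
Authors@R:
    person("Larvatax", "Developers", email = "larvatax@example.org",
           role = c("aut", "cre"))
Description: Analyzes multi-animal midline trajectories of Drosophila larvae
    crawling under directional or temporally varying light. Segments tracks
    into runs, reorientations (turns with head sweeps) and pauses using
    body-bend-angle hysteresis and per-animal speed thresholds, computes
    navigational parameters (navigation index, first head sweep direction
    and acceptance rates, turn direction, turn size and rate biases,
    steering within runs) with binomial standard errors, and applies the
    matching statistical battery (exact binomial, Fisher's exact, t tests,
    one-way ANOVA with Dunnett's test, Benjamini-Hochberg correction). An
    agent-based simulator with separable temporal (klinotaxis) and spatial
    (tropotaxis) sensory channels and eye-ablation states generates
    synthetic trajectories with ground-truth event logs.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
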