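# larvatax

Segmentation and navigational statistics for larval phototaxis
trajectories, with a ground-truthed synthetic-data generator.

## The problem

Drosophila larvae navigate light gradients with a run-and-turn strategy:
phases of forward crawling (**runs**) are interrupted by
**reorientations**, during which the animal slows down and probes the
environment with lateral **head sweeps**. A sweep followed by a run is
*accepted*; one followed by another sweep is *rejected*. Phototactic bias
can act through several separable knobs — the probability of accepting a
sweep given the intensity change sensed during it (klinotaxis, a
single-sensor temporal comparison), the side of the first sweep and the
curvature of runs (tropotaxis, an instantaneous left–right eye
comparison), turn sizes, and turn rates.

`larvatax` is for researchers analyzing multi-animal midline trajectories
from such assays (and for anyone validating that kind of analysis code).
It provides:

* **Stimulus models** — a planar directional gradient and a triangular
  temporal light ramp with plateau-exclusion phase labeling, plus the
  navigational compass (light = 0°, left positive) and its 90°/180° bins.
* **Segmentation** — body-bend-angle hysteresis (20° sweep initiation,
  10° termination, side-switch rule), per-animal iterative speed
  thresholds, 1 s minimum runs, track filters (≥ 0.5 cm, ≥ 30 s, first
  minute discarded), and accepted/rejected sweep labeling.
* **Metrics** — navigation index `mean(v_x) / mean(run speed)`
  (+1 toward, −1 away), first-sweep direction, turn direction, turn
  size/rate deltas between ramp phases, steering within runs, head-sweep
  sizes by outcome, run speed, all with binomial SEMs
  `sqrt(p(100−p))/sqrt(n)`.
* **Statistics** — exact binomial and Fisher 2×2 tests (small-probability
  summation, enumeration-verified), pooled/Welch t tests, one-way ANOVA
  with Monte-Carlo Dunnett comparisons, Benjamini–Hochberg adjustment.
* **Simulator** — an agent-based model with independent temporal and
  spatial sensory channels and eye-ablation states (`both`, `left_only`,
  `right_only`, `none`), emitting 13 fps midline trajectories plus
  frame-consistent ground-truth event logs.

## Worked example

Simulate two 11-minute temporal-ramp experiments (30 larvae each) with
the default biases, run the full analysis chain, and test the phase bias:

```r
library(larvatax)

ramp <- temporal_ramp()              # 0-380 uW/cm2, 25.5 s ramps, 11 cycles
sims <- simulate_experiments(
  sim_config(n_agents = 30, duration_s = 660, seed = 101,
             stimulus = ramp, n_experiments = 2))
segs   <- lapply(sims, function(s) segment_experiment(s$tracks))
report <- metrics_report(segs, ramp)
print(report)
```

```
accepted first sweeps, increase: 250 of 527 (47.4% +/- 2.18)
accepted first sweeps, decrease: 239 of 370 (64.6% +/- 2.49)
  n_runs                   619.5
  n_turns                  564.5
  run_speed_cm_s           0.06718
  turn_size_delta          13.86
  turn_rate_delta          0.6624
  ...
```

The generator accepted head sweeps with probability 0.65 during intensity
decrease and 0.45 during increase: the pipeline recovers 64.6 % and
47.4 % (each within ~1 SEM of truth). Turns are ~14° larger and ~0.66
turns/min/animal more frequent during light increase — the generated
temporal biases, measured back from raw midlines. The matching stats
table (Fisher's exact on the acceptance counts, two-sample t on the
per-experiment deltas, BH-adjusted):

```
                       comparison         test statistic   n        p     p_bh
1 acceptance increase vs decrease Fisher exact     0.495 897 4.37e-07 1.31e-06
2  turn size increase vs decrease two-sample t    13.830   4 5.19e-03 7.78e-03
3  turn rate increase vs decrease two-sample t     8.761   4 1.28e-02 1.28e-02
```

For directional-light assays use `directional_field()` and the spatial
metrics (`navigation_index`, `first_sweep_direction`, `turn_direction`,
`mean_steering`); `run_pipeline(experiment_bundle(...))` orchestrates the
whole chain, and `larvatax_main()` / `inst/cli/larvatax` expose
`simulate`, `analyze` and `report` subcommands (exit codes: 0 success,
2 validation failure, 3 empty after filtering).

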