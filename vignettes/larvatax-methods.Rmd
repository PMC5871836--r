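---
title: "Models and methods behind larvatax"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind larvatax}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(larvatax)
```

# The behavioral model

Drosophila larvae navigate by alternating two motor programs: *runs*
(forward crawling with head and body aligned) and *reorientations*, during
which the animal slows down and probes the environment with lateral *head
sweeps*. A head sweep that is followed by a run is *accepted* — the animal
commits to the new direction; a sweep followed by another sweep is
*rejected*. Phototactic bias can enter this loop through several distinct
knobs: the probability of accepting a sweep given the light change sensed
during it (a temporal, single-sensor comparison — klinotaxis), the side on
which the first sweep is launched and the curvature of runs (both driven
by an instantaneous left-right comparison between the two eyes —
tropotaxis), the size of turns, and the rate at which runs terminate.

`larvatax` implements the full measurement chain for this model —
trajectory segmentation, navigational metrics, and the statistical
battery — together with an agent-based generator whose two sensory
channels can be switched independently, so every metric can be validated
against a known ground truth.

# Segmentation

The segmentation input is a midline trajectory: per frame (13 frames/s),
an ordered tail-to-head list of midline points in cm. Three per-frame
quantities drive the state machine:

* **Body bend angle** — the signed angle between total-least-squares line
  fits of the posterior and anterior halves of the midline, split at the
  middle sample (shared vertex for odd counts). TLS makes the fit
  orientation-free; the sign is fixed tail-to-head, left positive.
* **Centroid speed** — frame-to-frame displacement of the midline
  centroid over the frame period, smoothed with a 5-frame centered moving
  average. Smoothing trades ~2 frames of onset resolution for robustness
  to tracking jitter at 13 fps.
* **Per-animal speed threshold** — see below.

A frame belongs to a run candidate when the body is aligned (|bend| <
20°) *and* the smoothed speed is at or above the per-animal threshold.
Maximal such intervals shorter than the 1 s minimum run time are merged
into the surrounding reorientation. Within reorientations, head sweeps
are detected with hysteresis on the signed bend: initiation at |bend| >
20°, termination when |bend| < 10°, when the sign flips while |bend| is
still above 10° ("head swings to the other side"), or when a run starts.
The last sweep of a reorientation followed by a run is accepted; all
others rejected. A final sweep cut off by the end of a track is labeled
`truncated` and excluded from acceptance-rate counts, since its outcome
is unknowable.

Run endpoint headings are computed from the net centroid displacement
over the first/last 0.5 s of the run rather than single-frame velocity
vectors; at 13 fps a single frame-to-frame vector is dominated by
measurement noise.

## The per-animal speed threshold

The defining description of the run/turn speed threshold is circular: the
threshold is the mean speed "immediately before and after
turning/pausing", but finding turns requires a threshold. We resolve this
iteratively: a provisional threshold (0.5 x median centroid speed)
segments the track once; the threshold is then re-estimated from the mean
smoothed speed in the 0.5 s windows flanking each detected reorientation,
and the loop repeats (at most 3 iterations). If no reorientation is
found, the provisional value is kept, with a warning.

One calibration deviates from the obvious choice deliberately: the
flanking windows sample *run* locomotion, so taking the refined threshold
equal to their mean (a scale factor of 1.0) puts the threshold numerically
on top of the run speed — in that regime measurement noise makes run
frames fail the `speed >= threshold` test about half the time and every
run fragments below the 1 s minimum. The refinement scale is therefore
0.8 by default (`thr_scale2`), placing the threshold at 80 % of the local
run speed, comfortably between run and reorientation speeds under any
noise level we simulate.

# Navigational metrics

All metrics follow the field's standard definitions. The navigational
compass puts the light source at 0°, away at 180°, and counts the
animal's left as positive, so at +90° the right body half faces the
light. The four 90°-wide compass bins use half-open intervals (closed on
the clockwise edge, e.g. toward = [-45°, 45°)) so that boundary angles
are assigned deterministically; the same rule puts 0° into the negative
half-disk of the 2-bin variant. These are measure-zero conventions.

* **Navigation index** — mean centroid velocity component toward the
  light divided by the mean run speed, pooled over run frames (+1 toward,
  -1 away, 0 unbiased). Whether the numerator should average over run
  frames only or all frames is ambiguous in the standard definition; we
  use run frames for both numerator and denominator, since the
  denominator is explicitly the mean *run* speed.
* **First head sweep direction** — away-vs-toward classification of first
  sweeps given the prior heading: in the perpendicular-bin mode only
  sweeps launched from the ±90° bins count (+90°: left is away); the
  half-disk mode admits every first sweep. Both modes are exposed because
  elevated-temperature assays yield too few perpendicular events.
* **Turn direction** — the sign of the wrapped heading change across a
  reorientation, mapped to away/toward by the prior bin, or reported as
  left/right for toward-heading turns. Zero net change is excluded.
* **Acceptance rate** — accepted fraction of first sweeps per ramp phase,
  with sweeps assigned to phases by their start time and the ±1 s
  exclusion margin around intensity plateaus applied.
* **Turn size / turn rate deltas** — per-experiment differences
  (increase minus decrease phase) of mean turn magnitude and of turns
  per minute per animal; the animal normalization integrates the number
  of concurrently active tracks over phase time.
* **Steering within runs** — the wrapped start-to-end heading change of
  runs whose circular-mean heading lies in a ±90° bin, sign-flipped for
  the -90° bin when pooling away-positive. Runs whose centroid comes
  within 0.5 cm of an arena wall are excluded from this metric only: the
  simulator (and any bounded arena) reflects headings at walls, and a
  reflection mid-run is indistinguishable from a large steer. With a
  photonegative population accumulating at the dark wall, including those
  runs reverses the sign of the pooled steering; interior runs recover
  the generative steering gain.
* **Binary SEM** — `sqrt(p(100 - p))/sqrt(n)` percentage points for all
  binary choice data.

Continuous metrics are aggregated per experiment first and averaged
across experiments second; binary metrics are pooled event counts.

# Statistics

Exact binomial and Fisher 2x2 tests use the small-probability summation
convention (the p-value sums all outcomes no more probable than the
observed one), matching the standard implementations; both are verified
in the test suite against brute-force enumeration (all 2^n sequences for
the binomial; all tables with fixed margins for Fisher). t tests default
to pooled variance (Welch optional). Dunnett's many-to-one comparisons
compute familywise-adjusted p-values from the joint null distribution of
the maximum absolute contrast statistic by seeded Monte-Carlo (1e5 draws
by default; the seed is recorded in each result), because no closed
quadrature is available in the dependency set. Benjamini-Hochberg
adjustment is applied within each user-declared comparison family; note
that BH adjusted *p-values* are not idempotent under re-adjustment — only
the rejection decision is — so the pipeline adjusts exactly once per
family.

# The synthetic-data generator

The simulator stands in for raw tracking data that has no public
accession. Its stated world: 30 agents per experiment on a 24.5 x 24.5 cm
arena, 11 minutes at 13 frames/s, 4 cm/min run speed, either a planar
directional gradient (4331 uW/cm² at the near edge, 103 uW/cm² per cm) or
a triangular temporal ramp (0-380 uW/cm², 25.5 s ramps, 4.5 s holds, 11
cycles). Behavioral defaults were chosen once for realistic event counts
and clear test power, not fitted to animal data, and are documented as
synthetic: acceptance probabilities 0.65 (decrease) / 0.45 (increase),
run-termination hazards 2 / 3 per minute by sensed intensity change,
sweep amplitude Normal(40°, 10°) floored at 25°, +15° extra amplitude for
turns accepted under increasing light, a logistic first-sweep side bias
of 1e-3 logits per uW/cm² of right-minus-left eye difference, and 6 °/s
of run curvature per unit normalized eye difference, always toward the
darker side (one centralized darker-is-preferred sign convention, so
ablation phenotypes emerge rather than being hard-coded).

The temporal channel is a two-point memory: the intensity sensed at sweep
start is compared with the intensity at the sweep peak, and the result
selects the acceptance probability. The true integration window of the
animal's comparison is unknown; the two-point scheme is the minimal
admissible choice. The spatial channel reads each eye through a
raised-cosine directional acceptance profile (half-width 90°) about an
axis tilted 45° forward of sideways; an ablated eye contributes zero.
In darkness or with both eyes ablated all gains act on zero input.

Two generator choices departed from the obvious design after
implementation proved it unworkable, both documented here deliberately:

1. **Sweep kinematics.** A half-cosine head excursion over 0.7 s moves
   the emitted centroid of a 0.4 cm body at up to ~0.09 cm/s — faster
   than the run speed — so runs and head-sweeping turns would be
   inseparable by any centroid-speed threshold. Head casts take 1.4 s
   (rise) + 0.7 s (return), within the range observed in real larvae.
2. **Centroid anchoring.** The emitted midline is recentered every frame
   so its centroid coincides with the agent's position. Without this, the
   instantaneous body realignment at sweep acceptance displaces the
   centroid by ~0.14 cm in a single frame (an apparent 1.8 cm/s spike)
   exactly where the threshold estimator samples "immediately after" the
   turn. With anchoring, centroid speed is purely locomotor — which is
   the quantity the analysis chain assumes it is measuring.

Agents reaching a wall are reflected specularly and tracks are never
truncated. Runs have a 1.5 s refractory period before the termination
hazard applies, keeping generated runs resolvable above the analyzer's
1 s minimum. Measurement noise is 10 um isotropic jitter per midline
point plus 4 °/sqrt(s) heading diffusion during runs.

## What a green test does and does not establish

The generator emulates the *statistical structure* the analysis assumes:
run/turn alternation, hysteresis-detectable head sweeps, stimulus-coupled
acceptance/direction/size/rate biases, and reproducible ground-truth
logs. It does not emulate peristaltic gait, body deformation during
turns, larva-larva collisions, tracking dropouts, or edge-following
behavior at walls. A green acceptance suite therefore establishes that
the measurement chain is faithful to the model and recovers known
parameters — not that real larvae obey the model, and not that the
original study's animal-derived percentages are reproduced (those require
the authors' raw data).

# Numerical conventions

Units are cm, s, degrees and uW/cm² throughout; angles wrap to
(-180°, 180°] with the boundary assigned to +180°. The ±1 s exclusion
margin around ramp plateaus is applied cyclically, so the first second of
a linear segment after a plateau is excluded symmetrically (the source
description is silent on this; symmetric dilation keeps the increase and
decrease label sets exactly equal in measure, 23.5 s per cycle each).
All randomness flows through a single integer seed per simulated
experiment; replicate experiments use consecutive seeds.
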