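---
title: "Methods: from 3D keypoints to gait and balance measures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from 3D keypoints to gait and balance measures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitbalance)
```

## What this package computes

Monocular-video pose estimators output per-frame 3D positions of a
17-joint skeleton, in arbitrary units and relative pose. `gaitbalance`
turns such trajectories into clinically interpretable gait and balance
measures, the way a marker-based laboratory would report them, and
provides the statistics used to validate one capture system against
another (ICC(2,k), Pearson r, Welch's t) plus k-means++ stratification of
a cohort into balance levels.

The measurement chain for one pre-edited straight-walk segment is:

1. **Centering.** The sacrum position is subtracted from every joint in
   every frame, making all coordinates body-relative.
2. **Metric scaling.** Each frame is multiplied by the ratio of the
   subject's measured shank length sum (left + right, a tape-measure
   quantity) to that frame's computed knee-to-ankle length sum. This
   resolves the scale ambiguity inherent to monocular reconstruction. The
   ratio is recomputed per frame by default; a trajectory-median variant
   (`ratio = "median"`) is available as a smoother alternative, since
   nothing in the method fixes which of the two a laboratory should
   prefer.
3. **Knee kinematics.** The knee angle is the included angle at the knee
   between the knee-to-hip and knee-to-ankle vectors (180° = straight
   leg). The angular velocity is the first difference times the frame
   rate, indexed to the later frame; no smoothing is applied before
   differencing (an optional moving-average window exists but is off
   everywhere in this package's own analyses).
4. **Steps.** The 3D inter-ankle distance is computed per frame; its
   local maxima at or above half the series maximum are steps, the peak
   value being the step length and the peak time the step time. Retained
   peaks must be at least 0.2 s apart (see *Numerical choices*). Step
   side is the foot whose ankle lies anterior to the coronal plane at the
   peak; step period is the difference of consecutive step times; walking
   speed is the two-step mean length over the period,
   v_i = (S_i + S_(i-1)) / (2 p_i).
5. **Gait events.** All local extrema of the knee angular velocity are
   found; maxima at or above the 80th percentile of the velocity values
   and minima at or below the 20th percentile are retained. Each retained
   minimum is a toe-off. From each retained maximum the first subsequent
   sample below 10°/s is a heel-strike. Swing time is a heel-strike minus
   the most recent preceding toe-off of the same leg; support time is a
   toe-off minus the most recent preceding heel-strike. Records without
   the required predecessor (recording boundaries) carry no value.
6. **Centre of mass.** An 11-segment model (head, upper and lower trunk,
   bilateral upper arms, forearms, thighs, shanks; hands and feet
   excluded as the lightest parts) places each segment COM a fixed
   fraction along its proximal-to-distal line and combines them with
   segmental mass fractions. The relative COM velocity (RCOMV) is the
   frame-rate-scaled magnitude of the per-frame COM displacement after
   subtracting a reference point: the left ankle in system-validation
   work, the sacrum (hip region) in measurement work. Per-frame unsigned
   distances from the COM to the sagittal plane (through the sacral,
   thoracic and cervical spine points) and to the coronal plane (through
   the sacrum, perpendicular to both the sagittal plane and the spine
   axis) summarise balance as max − min deviation ranges.

The validation workflow (`run_validate()`) adds: resampling the gold
system to the test frame rate (linear interpolation), temporal alignment
by integer-lag cross-correlation of the left-knee-angle series, trimming
both trajectories to the aligned overlap, and per-parameter ICC(2,k)
(targets = segments, raters = the two systems) and Pearson r with the
conventional qualitative bands (ICC: < 0.40 poor, 0.40–0.60 fair,
0.60–0.75 good, ≥ 0.75 excellent; r: < 0.30 negligible, 0.30–0.50 low,
0.50–0.70 moderate, 0.70–0.90 high, ≥ 0.90 very high). How to arrange an
n × k matrix for ICC(2,k) is a workflow decision, not part of the
statistic; this package's validation workflow uses segments as targets
and systems as raters.

## Tunable parameters

| Parameter | Default | Unit | Why this default |
|---|---|---|---|
| `threshold_fraction` | 0.5 | — | discards sub-half-maximum inter-ankle peaks; mid-swing distances stay well below half of the double-support peak |
| `min_separation_s` | 0.2 | s | no gait produces two step peaks within 200 ms; keypoint noise otherwise splinters one peak into jitter maxima (floor: 2 frames) |
| `heel_strike_threshold` | 10 | °/s | the knee is essentially still at foot contact; 10°/s separates terminal-swing extension from stance |
| `q_low`, `q_high` | 0.2, 0.8 | — | percentile gates that keep one flexion minimum and one extension maximum per stride and reject small extrema |
| `ratio` (scaling) | `"frame"` | — | the per-frame form follows the scaling definition literally; `"median"` resists single-frame depth errors |
| `com_variant` | `"normalized"` | — | Σ m_i COM_i / Σ m_i is the standard segmental method; the `"printed"` variant (1/N prefactor, whole-body mass in the denominator) is kept selectable for fidelity testing but is not a centroid, because only 11 of the body's segments enter the sum |
| `reference` (RCOMV) | `"sacrum"` | — | body-relative COM velocity for measurement; `"left_ankle"` for validation against marker systems with well-tracked foot markers |
| `k`, `seed`, `n_init` (clustering) | 3, —, 10 | — | three balance levels (healthy-like, higher and lower recovery); 10 restarts keeping the lowest within-cluster sum of squares is the standard guard against poor local optima |

Segment mass fractions ship as an editable table
(`default_segment_table()`, `inst/extdata/segment_table.csv`) with values
from a published adult segmental table (trunk split into an upper and a
lower segment) and midpoint COM positions; replace it with
population-specific standards where available.

## The simulator: what it emulates, and what it does not

`generate_walk()` produces a straight, constant-pace walk of the
17-joint skeleton with every downstream answer known:

* Feet advance alternately; the peak 3D inter-ankle distance of every
  step equals `step_length` exactly in continuous time (and exactly at a
  sampled frame whenever the step times land on the frame grid, e.g.
  0.6 s steps at 30 Hz). The final partial swing is parked at 65%
  progress so the series ends below the peak threshold instead of on a
  spurious plateau.
* Each knee traces one flexion–extension cycle per stride between
  `180° − knee_rom` and 180°, built from a warped cosine with short
  dwells at peak flexion and full extension — so the sampled series
  attains both extremes exactly — and a steep "toe-off burst" around the
  angular-velocity minimum, so the discrete minimum falls on the
  programmed toe-off instant. The heel-strike node is placed where the
  continuous angular velocity crosses the canonical 10°/s threshold.
  Programmed toe-off and heel-strike times are recorded as ground truth.
* The whole-body COM sways relative to the body's sagittal plane with
  the configured lateral amplitude at stride frequency (the recoverable
  deviation range is exactly twice the amplitude) and with twice that
  amplitude anteroposteriorly at step frequency, reflecting that AP sway
  normally exceeds ML sway. The sway is applied as a common offset to
  every joint except the three spine points that define the planes, with
  a gain derived from the segment table so the COM excursion is exact.
* `generate_sts()` produces a seated hold, a smooth monotone rise, a
  standing hold and a descent, with exactly constant sacrum height in
  the holds and a monotone knee angle (≈ 90° seated to 180° standing)
  during the rise.

It is a **kinematic pattern generator, not a biomechanical model**: limb
trajectories are stylized waveforms with mutually consistent extractor
targets, not forces or physiological coordination. Foot-ground contact
states, double-support timing, turning, arm swing and pose-estimator
error structure (depth-correlated, occlusion-driven, autocorrelated) are
not simulated; keypoint noise is isotropic white Gaussian. Passing
round-trip tests therefore demonstrates that the extraction chain is
correct and internally consistent — not that it is robust to the failure
modes of real pose estimators.

The recovery study run by the tests and the acceptance script uses 20
walks spanning step lengths 300–650 mm, step periods 0.5–0.9 s and knee
ROM 40–80°, with keypoint noise cycling through 0, 0.05, 0.1 and
0.15 mm. The sub-millimetre noise levels are where event-level ground
truth stays meaningful: noise propagates to the knee angle at roughly
0.26° per millimetre of keypoint noise, and a max − min statistic over a
10 s segment gains an upward bias of about 1.5° per millimetre, so
millimetre-scale noise would swamp a 1° ROM comparison by construction
rather than reveal anything about the code. Percentile-based extremum
retention has a related sensitivity: because any angular-velocity
waveform spends long spans near zero around its angle extremes, the
20th/80th percentile gates sit close to zero and noise wiggles can clear
them — a real weakness of the rule on noisy data, visible in this
package's own experiments and mitigated in practice by smoothing (not
applied here) or stronger gates. Event-time comparisons score detected
events lying within the time span of the ground-truth events; a
recording that starts or ends mid-stride yields boundary events whose
true counterpart falls outside the recorded window.

## Numerical choices

* Angle computation clamps cosines to [−1, 1] before `acos`; zero-length
  thigh or shank segments raise a degenerate-geometry error naming the
  frame.
* Cross-correlation uses mean-removed signals at integer lags with at
  least 50% overlap; C(τ) = Σ_t x(t)·y(t − τ), so a copy of x delayed by
  k gives τ_max = −k ("shifting y forward by k maximises overlap"). Ties
  break toward the smallest |τ|, then the negative lag. Constant or
  all-zero signals raise an undefined-alignment error.
* Percentiles use the linear-interpolation definition
  (`stats::quantile`, type 7).
* Step-peak detection treats a run of equal values flanked by lower ones
  as a single peak at its central frame: a peak falling exactly midway
  between two samples produces a two-sample plateau that a strictly-
  greater comparison would miss. Constant series yield no steps.
* Where consecutive retained velocity extrema of the same kind occur
  with none of the other kind between them, only the most extreme
  survives, so toe-offs and heel-strike seeds alternate.
* The anterior direction for step side is the horizontal sacrum
  displacement over the enclosing step interval, which requires the
  lab-frame trajectory (the pipeline passes the pre-centering input):
  after sacrum centering the displacement vanishes and the two ankles
  move exactly symmetrically, leaving no motion cue. With no usable
  displacement the horizontal coronal-normal is used as-is, with
  documented arbitrary orientation. Ankles whose signed distances differ
  by under 1 mm raise an ambiguity warning and the larger magnitude
  wins.
* k-means++ uses squared-Euclidean distances on z-scored features
  (scale heterogeneity across mm, s and °/s would otherwise let one
  column dominate; disable with `standardize = FALSE`), Lloyd iterations
  until the largest centroid shift is below 1e-8 or 300 iterations, an
  empty cluster re-seeded at the point farthest from its centroid, and
  10 seeded restarts keeping the lowest final within-cluster sum of
  squares. Cluster levels are labelled by descending centroid walking
  speed, since "healthy-like" gait is the fastest; the mapping from
  clusters to clinical labels is otherwise a human decision.
* ICC(2,k) is computed directly from the two-way ANOVA mean squares,
  (MS_rows − MS_error) / (MS_rows + (MS_cols − MS_error)/n); a matrix
  with zero total variance raises an undefined-ICC error rather than
  returning 0/0.
* Swing/support subscripting: the event-difference definitions are only
  self-consistent when read as "minus the most recent preceding event of
  the other kind", which also makes consecutive swing + support of one
  foot equal that foot's stride time; that reading is implemented.

## Known limitations

* Segment selection (trimming a recording to straight-walk segments) is
  manual: one input file is one pre-edited segment. Turning is neither
  simulated nor handled.
* The reference group summaries bundled for Welch comparisons and
  synthetic cohorts are segment-level group means and SDs; the synthetic
  cohort draws columns independently, so between-parameter correlations
  of real gait data are absent. Published RCOMV group summaries carry an
  unexplained scale discrepancy between the validation context
  (≈ 900 mm/s) and the measurement context (≈ 6–7 mm/s); both arise from
  the same RCOMV definition in this package and no reconciliation is
  attempted.
* ICC and r on simulated gold/test pairs characterise the pipeline under
  constructed perturbations (delay, white noise); they do not reproduce
  any published system-validation value, which would require the original
  recordings.
* Range (max − min) statistics — knee ROM, angular-velocity range, COM
  deviation ranges — are upward-biased by measurement noise; comparisons
  across systems with different noise levels inherit that bias.
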