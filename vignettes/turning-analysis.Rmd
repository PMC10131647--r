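---
title: "Turning-while-walking analysis: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Turning-while-walking analysis: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(turnkin)
```

## The problem

Turning while walking requires a coordinated, top-down reorientation of the
body about the vertical axis: the head turns first, then the sternum, then
the pelvis. When segments reorient almost simultaneously and with small
relative angles — *en bloc* turning — the behaviour is associated with
elevated fall risk, and it appears in ageing and in several neurological
conditions. The experimental paradigm this package analyses is a 30-second
walk up and down a 5 m walkway at self-selected speed, which forces repeated
180° turns, performed as a single task (ST) and under two smartphone-based
cognitive loads (a simple reaction-time task, SDT, and a numerical Stroop
task, CDT).

`turnkin` turns raw optical motion-capture marker trajectories (200 Hz;
3-marker clusters on head, sternum and pelvis, heel and toe markers on both
feet) into:

* **general** turn measures — turn duration, steps while turning;
* **segmental** measures — peak angular velocity per segment;
* **intersegmental** measures — relative turning onset latency and maximum
  intersegmental angle for the three cranial–caudal segment pairs;
* **dual-task cost** (DTC) of the general and segmental measures; and
* the group × condition **mixed-ANOVA layer** over a cohort.

Because no raw cohort recordings are publicly deposited for this paradigm,
the package ships a first-class synthetic-trial generator with exact ground
truth; every detector is validated by parameter recovery against it.

## From markers to segment yaw

Each segment's orientation is estimated per frame as the least-squares rigid
rotation (orthogonal Procrustes, solved by SVD with the usual reflection
guard) from the cluster's configuration at the first valid frame — or an
explicit calibration configuration passed as `reference` — to the current
frame. Yaw is the Euler z angle of that rotation in a z–y–x sequence,
`atan2(R[2,1], R[1,1])`, extracted first so pitch and roll (which are not
analysed) only affect it through rigid-fit residuals. The yaw series is
unwrapped so that a continuous rotation through ±180° never folds back.

Numerical notes:

* The reference cluster must not be collinear; the second singular value of
  the centred configuration is checked against `1e-8` of the first.
* Occlusions travel through the pipeline as `NA`. Gaps of at most 10 frames
  (50 ms at 200 Hz) are bridged by linear interpolation — standard mocap
  practice; anything longer stays invalid and later invalidates any turn
  that would contain it. Samples are never invented.

Angular velocity is obtained by zero-phase 4th-order Butterworth low-pass
filtering (default cutoff 6 Hz: turning dynamics live below ~2 Hz, marker
jitter above) followed by central differences. The filter uses
odd-reflection padding and is applied about the run's start value, so
constants are reproduced exactly and edge transients are suppressed; runs
too short to pad are passed through unfiltered.

## Turn detection

At the start and end of a turn the yaw signal's local mean shifts abruptly.
The detector therefore works on mean-shift change points:

1. `best_single_split()` finds the split minimising the summed two-region
   residual sum of squares — the point where the mean changes most;
2. `detect_change_points()` applies it recursively (binary segmentation),
   accepting a split only when it lowers the cost by more than a penalty.
   The default penalty is BIC-style, `3·σ̂²·log T`, with `σ̂` estimated
   robustly from the median absolute first difference — on a 30 s trial
   this accepts the four plateau shifts and rejects noise. A small
   numerical floor (`1e-10` of the total RSS) keeps floating-point jitter
   on exactly constant plateaus from being segmented;
3. `detect_turns()` classifies the induced regions as plateau or transition
   by mean absolute yaw rate (threshold 20 °/s), merges consecutive
   same-class regions, and emits one turn per transition run whose bounding
   plateau levels differ by at least 90° (the paradigm contains only ~180°
   turns). Plateau levels are medians over the plateau runs, which makes
   them robust to slow transition tails that the segmentation sometimes
   attaches to a plateau.

By default the boundaries are then *refined* to the samples where the
filtered yaw first departs from the pre-turn plateau by 5% of the
plateau-to-plateau change (and symmetrically 95% at the end). The crossing
of a steep yaw ramp localises the onset far better than the raw
change-point grid — noise-free simulations recover configured latencies to
the sample, and with 2 mm marker noise 95% of latencies land within 10–15
ms. `refine = FALSE` restores the raw bounding change points.

A structural consequence of boundary placement inside the smooth transition
is that the reported magnitude `|yaw(end) − yaw(start)|` is *systematically
below* the nominal 180°: with the default 5%/95% convention about 90% of
the plateau difference (~162°). This mirrors what happens when mean-shift
partitioning meets an ellipse-like, non-abrupt turning trajectory, and is a
property of the method, not a bug; it cancels from all between-condition
contrasts.

## Gait events and steps while turning

Initial contact is a prominent local minimum of the toe marker's vertical
velocity; final contact a prominent local maximum of the heel marker's.
Peaks are selected by topographic prominence (default 0.2 m/s) with a
minimal same-kind spacing of 0.3 s, and a repair pass drops the less
prominent of two consecutive same-kind events so contacts alternate. Steps
while turning are the initial contacts of both feet inside the *pelvis*
turn window — the pelvis being the most whole-body-representative of the
three segments — counted over the half-open interval `[start, end)` so
adjacent phases never double-count.

## Intersegmental coordination measures

For each matched pair of turns (greedy matching across segments within
1.5 s and equal direction):

* **onset latency** = `start(cranial) − start(caudal)`; negative exactly
  when the more cranial segment started first. Latencies are averaged
  signed, are antisymmetric under role swap, and satisfy
  `latency(head→pelvis) = latency(head→sternum) + latency(sternum→pelvis)`
  identically.
* **maximum intersegmental angle** = the largest absolute difference of the
  two yaw signals over the union of the pair's turn windows, after each
  signal is re-referenced to its pre-turn plateau mean (a 0.5 s window
  ending 0.1 s before the earlier turn start) so static posture offsets
  cancel. Both signals are smoothed with the pipeline's 6 Hz low-pass
  before differencing; without smoothing, the maximum of ~2000 noisy
  differences has a noise floor of several degrees, with it the en bloc
  floor is below 1° at 2 mm marker noise.

## Dual-task cost

DTC compares each measure between ST and a dual-task condition:
`100·(ST − DT)/ST`, so a dual-task-related drop in a higher-is-better
measure (peak angular velocity) yields a positive cost. The printed form of
the source equation was not recoverable, so the convention is explicit and
a flag (`orientation = "raw_change"`) exposes `100·(DT − ST)/ST` for
lower-is-better measures; the two differ only by sign and every invariant
(scale invariance, `dtc(st, st(1−x)) = 100x`) holds under either.

## The statistics layer

`mixed_anova()` fits the split-plot design — `group` between subjects,
`condition` within — through `stats::aov` with an `Error(subject)` stratum,
optionally adjusted for gait speed. Gait speed varies with condition, so by
default it enters per subject × condition (grand-mean-centred);
`covariate = "subject_mean"` switches to a pure between-subject adjustment.
Greenhouse–Geisser ε and Mauchly's sphericity test are computed from the
pooled within-group covariance of the subject × condition matrix
(cross-checked against `car::Anova` in the test suite); the ε-corrected p
is applied to the within-subject effects when Mauchly is significant at
.05. ε is estimated from the raw response, ignoring the covariate — with
three conditions and the cohort sizes involved the difference is
negligible. Post hoc pairwise t tests (paired across conditions, pooled
two-sample across groups) are Bonferroni-adjusted and, by convention, run
only after a significant omnibus effect.

One caveat the test suite documents: ε-shrinking both degrees of freedom
*lowers* the tail probability when F is small (the corrected and
uncorrected F distributions cross near F ≈ 1), so "the corrected p is
larger" is asserted — and true — in the rejection region.

Gait speed itself is the mean horizontal speed of the pelvis-cluster
centroid over straight-walking intervals, i.e. outside detected pelvis
turns extended by a 0.25 s guard band.

## The synthetic-trial generator

`simulate_trial()` produces marker data with exact ground truth:

* **Yaw**: a staircase of plateaus (0°, ±180°, alternating with the up/down
  walking direction) joined by smooth transitions. The transition is a
  quintic smoothstep — C²-continuous, compactly supported, exactly on the
  plateaus outside its support, with analytic peak rate
  `1.875·M/D` — parameterised by its 5–95% duration (default 2.0 s per
  segment). A logistic was considered and rejected: its infinite support
  either never reaches the plateaus or introduces derivative spikes when
  clamped.
* **Latencies**: each segment's transition starts a configurable delay
  after the head's (defaults 80 ms sternum, 180 ms pelvis — the healthy
  top-down pattern).
* **Path**: the walker advances at the configured speed (default 0.8 m/s,
  typical of mixed clinical cohorts on a turning-rich task) along the
  current pelvis heading, so turns trace realistic arcs; a warning is
  raised if the path outgrows the walkway.
* **Markers**: anatomically plausible rigid 3-marker clusters (head,
  sternum, pelvis) are rotated by their segment's yaw and carried along the
  path; heel/toe markers get vertical velocities built from Gaussian bumps
  centred *exactly* on the scheduled contacts (cadence 1.8 steps/s, 60%
  stance), so gait-event ground truth is exact by construction.
* **Noise**: i.i.d. Gaussian noise (default SD 2 mm, typical optical
  mocap marker jitter) on every coordinate; a fixed seed makes the trial
  bit-reproducible.

Ground truth records both the full transition support (`start_s`, `end_s`)
and the 5–95% boundaries (`start_5_s`, `end_95_s`) matching the detector's
reporting convention — recovery tests compare like with like.

`simulate_cohort()` layers per-subject lognormal multipliers (duration,
latency, speed; SD 0.1 on the log scale) over group configurations and
per-condition effect scalings (e.g. shrinking latencies under CDT to mimic
en bloc behaviour), reproducibly under one master seed.

What the generator deliberately does **not** model: musculoskeletal or
balance dynamics, soft-tissue artefact, pitch/roll excursions, asymmetric
or on-the-spot turns, and the cognitive mechanism of dual-tasking (only its
kinematic consequences via parameter shifts). Passing recovery tests on
simulated trials therefore demonstrates correctness of the *algorithms
under the stated signal model*, not clinical validity on real recordings.

## Problem sizes used in the tests

The validation suite runs, among others: 1000 random signals against an
exhaustive single-split oracle and 1000 staircase signals against a
dynamic-programming optimal-segmentation oracle; 100 noise-free and 100
noisy (2 mm) full trials for latency, gait-event and step-count recovery;
a 4-point latency grid for the en bloc limit; and 1000 simulated null
cohorts (3 groups × 8 subjects × 3 conditions) for the type-I calibration
of the mixed ANOVA. These sizes give Monte-Carlo standard errors well below
the asserted tolerances while keeping the full suite in the minutes range
on a single CPU.

## Known limitations

* Detected turn magnitude underestimates the nominal rotation by
  construction (see above); compare magnitudes only within one boundary
  convention.
* The binary-segmentation detector is exact against the optimal
  segmentation in the high-signal regime the paradigm produces (plateau
  shifts of tens of degrees over sub-degree noise) but, like any greedy
  segmentation, can differ from the global optimum on low-signal inputs.
* The CSV dialect and the C3D subset (Intel byte order, labelled 3D
  points) cover the pipeline's needs; analog channels, DEC/MIPS byte
  orders and force-plate data are out of scope.
* With a within-cell covariate the ANOVA is an ANCOVA on the same error
  strata; ε and Mauchly come from the unadjusted responses.

## A worked example

```{r example, eval = FALSE}
cfg <- simulation_config(seed = 42)
sim <- simulate_trial(cfg)
an <- analyze_trial(sim$trial)
an$metrics[, c("duration_s", "n_steps", "latency_sternum_head",
               "latency_pelvis_head", "magnitude_head")]

# cohort-level: en bloc shift under the complex dual task
coh <- simulate_cohort(cfg, n_subjects = c(young = 5, pd = 5),
                       effects = list(CDT = list(latency_scale = 0.3)),
                       seed = 1)
tab <- cohort_table(lapply(coh, function(e) analyze_trial(e$trial)$metrics))
mixed_anova(tab, "latency_sternum_head")
```
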