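# turnkin

Turning-while-walking kinematics from optical motion capture: per-segment
turn detection, intersegmental coordination, dual-task cost and the
group × condition statistics layer.

## What it is for

Turning during walking demands a top-down reorientation of head, sternum
and pelvis about the vertical axis; turning *en bloc* — segments rotating
nearly simultaneously with small relative angles — is associated with
elevated fall risk in ageing and neurological disease. `turnkin` implements
a complete analysis pipeline for the standard lab paradigm (30 s of walking
up and down a 5 m walkway at self-selected speed, hence repeated 180°
turns, performed alone and under smartphone-based cognitive dual tasks),
aimed at movement scientists and clinical gait researchers.

From marker trajectories (C3D or a documented wide CSV dialect, 200 Hz) it
computes per trial:

* segment yaw ψ(t) per body segment from its marker cluster, as the Euler
  z angle (z–y–x sequence) of the per-frame least-squares rigid rotation
  (orthogonal Procrustes) from a reference configuration, unwrapped;
* turn events per segment via mean-shift change-point detection: binary
  segmentation over splits k minimising RSS(x₁..ₖ) + RSS(xₖ₊₁..ₜ) with a
  BIC-style penalty, plateau/transition classification by yaw rate, and
  boundary refinement to the 5%/95% crossings of the plateau-to-plateau
  change;
* turn duration, steps while turning (initial contacts — prominent minima
  of toe vertical velocity — inside the pelvis turn window), peak angular
  velocity per segment;
* intersegmental onset latencies, start(cranial) − start(caudal), negative
  when the cranial segment leads, and maximum intersegmental angles
  max |ψ_cranial(t) − ψ_caudal(t)| after pre-turn re-referencing;
* dual-task cost DTC = 100·(ST − DT)/ST per measure and subject;
* mixed (split-plot) ANOVAs with a gait-speed covariate,
  Greenhouse–Geisser correction and Bonferroni post hocs over a cohort.

A synthetic-trial generator with exact ground truth (smoothstep yaw
transitions with configurable top-down latencies, parametric gait cycles
whose velocity extrema sit exactly on the scheduled contacts, Gaussian
marker noise) backs the validation suite and supports power studies. See
the methods vignette (`vignettes/turning-analysis.Rmd`) for the models,
defaults and limitations.

## A worked example

```r
library(turnkin)

cfg <- simulation_config(seed = 42)   # 30 s, 4 x 180 deg turns, 2 mm noise
sim <- simulate_trial(cfg)
an  <- analyze_trial(sim$trial)
an
#> <trial_analysis> 4 matched turns, gait speed 0.80 m/s
#>   mean turn: 1.99 s, 3.5 steps, 162 deg (pelvis)

round(t(an$metrics[, c("duration_s", "n_steps", "gait_speed_mps",
                       "peak_omega_head", "latency_sternum_head",
                       "latency_pelvis_head", "max_angle_pelvis_head",
                       "magnitude_head")]), 3)
#> duration_s              1.993
#> n_steps                 3.500
#> gait_speed_mps          0.800
#> peak_omega_head       109.160
#> latency_sternum_head   -0.081
#> latency_pelvis_head    -0.181
#> max_angle_pelvis_head  17.824
#> magnitude_head        161.756
```

Reading the numbers: the configured onset latencies (sternum 80 ms, pelvis
180 ms after the head) are recovered as signed latencies of −0.081 s and
−0.181 s — negative because the cranial segment starts first; the detected
magnitude (161.8°) sits below the nominal 180° because the change-point
boundaries lie inside the smooth transition, a known systematic property of
this detector family; gait speed matches the configured 0.8 m/s.

Cohort-level analysis chains the same pieces:

```r
coh <- simulate_cohort(cfg, n_subjects = c(young = 5, pd = 5),
                       effects = list(CDT = list(latency_scale = 0.3)),
                       seed = 1)
tab <- cohort_table(lapply(coh, function(e) analyze_trial(e$trial)$metrics))
mixed_anova(tab, "latency_sternum_head")     # group x condition, GG-corrected
dtc_table(tab)                               # per-subject dual-task cost
```

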