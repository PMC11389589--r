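---
title: "Measuring hand-localization precision during early visuomotor adaptation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring hand-localization precision during early visuomotor adaptation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the paradigm

When people reach under a visuomotor rotation — the cursor standing in for
their unseen hand is rotated (here by 45°) relative to the true movement —
two learning processes unfold: deliberate re-aiming (an explicit strategy)
and implicit, error-driven recalibration, whose hallmark is the aftereffect
that persists once feedback is veridical again. Both interact with *position
sense*: how precisely people can localize their unseen hand. `vmrloc`
implements the full analysis path for paradigms that probe this precision
*early* in learning, when strategies dominate.

The design alternates short **adaptation cycles** (rotated cursor) with
**washout cycles** (veridical cursor). Each cycle holds 2–4 reaches in
total; the last reach is performed without any feedback, after which the
hand is localized either with a **pointer** (a continuous position report,
scored 100 points at 0 cm error down to 0 points at ≥ 10 cm) or by a
**two-alternative forced choice** (2AFC) judgment of a probe displayed at
±3.33°, ±10°, or ±20° from the true hand position along a 140° arc.
Because each cycle restarts early adaptation, pooling the once-per-cycle
localizations across many cycles yields enough repetitions to estimate both
the *bias* (shift toward the rotated cursor) and the *dispersion* (inverse
precision) of perceived hand position separately for adaptation and washout.

Three layouts are built in:

* `exp1` — rotation alternates CW/CCW between adaptation cycles; two
  targets 45° apart (bases 20° and 65°, ±7.5° jitter per cycle); the
  instructed strategy aims at the *hand target* so the cursor slices the
  *cursor target*.
* `exp2` — CCW only, a single target at 45° (±15° jitter), aim-direct
  instruction: learning is purely implicit.
* `exp3` — CCW only, like `exp1` but localization trials are cued in
  advance (pointer method, 3 blocks).

## Analysis pipeline

`run_pipeline()` chains the stages in the order the measurements require:

1. **Kinematics** (`reach_features()`): movement onset is the first sample
   at which speed exceeds 5 cm/s *and* the hand is more than 0.5 cm from
   home; offset is the first drop below 5 cm/s after the first post-onset
   speed peak. Direction is the angle of the hand relative to home at peak
   speed; extent is the endpoint's radial distance; curvature is the
   linearity index (LI), the maximum perpendicular deviation from the
   home–endpoint line divided by extent. Signed directions are positive CW
   in CCW-only designs and positive toward expected adaptation in `exp1`.
2. **Screening** (`screen_reaches()`, `screen_pointer_reports()`): reaches
   are rejected when the 10 cm target radius takes more than 300 ms to
   cross, when LI > 0.2, or (two-target design only) when the movement
   heads more than 30° away from the instructed aim on the wrong side.
   Pointer reports are rejected when the reported radius is under half the
   actual extent (premature pedal presses) or the radial error exceeds
   twice the subject's overall radial-error SD — one pass, with the SD
   stored so re-screening is idempotent.
3. **Pointer analysis** (`compute_bias()`, `compute_iqr()`): angular errors
   (reported minus actual direction, both from home) are sign-corrected so
   positive always means "toward the rotated cursor", averaged into per-bin
   biases, and their interquartile range — robust to outliers — is taken
   after removing each target's own bias. Bins are subject × cycle type ×
   reach number (= cycle length), plus a pooled bin.
4. **Psychometrics** (`fit_psychometric()`): per subject and cycle type, a
   binomial GLM with logit link models P(probe judged "left") against probe
   offset. `PSE = -intercept/slope` is the bias; `JND = 2 ln 3 / slope` the
   dispersion. With two targets the per-target PSE is subtracted from the
   offsets first (`align_and_pool()`), so the pooled curve measures
   dispersion uncontaminated by opposite-sign biases.
5. **Variability matching** (`match_variability()`): a control that equates
   actual hand-position variability between cycle types by iteratively
   removing the most extreme adaptation trial and the most average washout
   trial until the adaptation hand-position IQR falls just below the
   washout one, then re-computes localization IQRs on the survivors. If the
   localization-dispersion difference survives matching, it cannot be an
   artifact of more variable hand positions.

All inferential statistics are out of scope by design: the pipeline exports
tidy per-subject tables (`out_dir` CSVs) that any stats package can consume.

## The simulator: what it emulates, and what it does not

`simulate_experiment()` generates synthetic participants so that every stage
above can be validated against known ground truth. Implicit adaptation is a
single-state linear state-space learner per hand target,

$$x_{t+1} = A\,x_t - B\,e_t,$$

with retention $A = 0.95$ and learning rate $B = 0.15$ per reach, driven by
the visual error $e_t$ of the cursor relative to the aim point; no-feedback
reaches apply retention only. Under a constant rotation $r$ the state
converges to $x^* = -B r / (1 - A + B)$ (−33.75° at the defaults), and
aftereffects grow with the number of preceding rotated reaches — the
qualitative signature the kinematic analysis must recover. Trajectories are
minimum-jerk paths (10.5 ± 0.3 cm in 350 ms at 1 kHz), which satisfies the
300 ms-to-radius task constraint; `"slow"` and `"curved"` presets produce
screening fodder.

The report parameters are the *study conditions* of the package's tests and
were fixed once from the magnitudes such experiments report: localization
bias 2° (adaptation) vs 0.5° (washout) toward the cursor; angular report
noise 7.84° vs 4.46° SD (equivalently IQRs of ≈ 10.6° and 6.0° via
IQR = 1.349σ, baseline 5.03°); 2AFC slopes 0.211 and 0.320 log-odds/°
(JNDs ≈ 10.4° and 6.9°); motor noise 2.8° SD plus 7.8° SD of extra aiming
scatter on strategy-mode adaptation reaches, which reproduces the large
adaptation/washout gap in actual hand-position variability that the
matching control exists to rule out.

Deliberate omissions: the simulator does not model late-stage strategy
adjustment, participant exclusions, reaction times, or any correlation
between localization error and hand position (reports scatter around the
true endpoint). Consequently, passing recovery tests shows the *pipeline* is
unbiased and correctly plumbed at realistic n — it does not show that human
data obey the generator's assumptions, and post-matching localization IQRs
in simulation stay at their generative values rather than shrinking as
correlated human reports might.

## Numerical choices

* **Angles**: degrees, 0° straight ahead, positive CCW, wrapped to
  (−180, 180]; positions in cm with home at the origin; time in ms.
* **Quartiles**: type-7 (linear interpolation) throughout, switchable via
  `qtype` — the convention materially affects IQRs at n ≈ 36 per bin.
* **Speed**: central differences without smoothing (simulated traces are
  clean); a `smooth_fun` hook exists for real recordings, off by default.
* **Peak speed tie-break**: first global maximum within onset–offset.
* **Offset search** starts after the first post-onset speed peak, so
  sub-threshold jitter at onset cannot truncate the movement; if speed
  never drops below threshold the last sample is used and flagged.
* **Separation** in psychometric fits triggers a weak ridge penalty
  (λ = 0.01 on the slope) and a flag; a non-positive slope yields an
  infinite JND and a degeneracy flag rather than a silent nonsense value.
* **Matching granularity**: one trial removed per cycle type per iteration,
  ranked by absolute deviation from the running median, ties broken by the
  earlier trial index; the stop rule is strict (`adaptation IQR <
  washout IQR`) and a floor of 8 trials per type turns pathological inputs
  into a diagnosable failure result instead of an error.
* **Premature-press reading**: "radial errors less than half the movement
  extent" is implemented as *reported radius* < 0.5 × extent; the literal
  error-magnitude reading would reject nearly every good report.
* **2×SD outlier scope**: computed per subject (config-switchable to
  pooled), once, before any removal; an SD of exactly 0 defines no
  outliers.
* **Jitter** is redrawn per cycle; `exp1`/`exp3` washout cycles inherit the
  preceding adaptation cycle's jittered target (their required direction is
  the same), `exp2` washout cycles draw their own.
* **Left/right coding**: "left" = CCW of the hand on the arc given the
  workspace orientation; the convention is a documented sign choice and can
  be flipped by negating probe offsets.

## Problem sizes used in the tests

The packaged checks run the generator at study scale — 15 subjects ×
(baseline + 6 blocks) for the pointer arm and 14 subjects × 7 blocks for
the 2AFC arm, 20 seeds for the seed-averaged recovery suite — with
endpoint-level kinematics; full 1 kHz trace synthesis and event detection
are exercised on smaller runs and on 100 single traces against an
exhaustive sample-scan oracle. Psychometric recovery uses the design's
2,520 trials per fit, asserted on means across replicate draws so the check
measures estimator accuracy rather than one sample path.

## Worked example

```{r, eval = FALSE}
library(vmrloc)

cfg <- experiment_config("exp1", localization_method = "pointer")
ds  <- simulate_experiment(cfg, sim_params("exp1", seed = 1),
                           n_subjects = 15)
rep <- run_pipeline(ds)
rep$group_localization   # bias and IQR by cycle type, across subjects
attr(rep$aftereffects, "group")
rep$match_summary        # variability-matching control, per subject
```

## Known limitations

* The deposited-data loader expects the package's own CSV layout; mapping
  an external dataset requires renaming columns to the documented schema.
* The learner omits strategy re-adjustment dynamics, so simulated cursor
  errors lack the early-vs-late asymmetry real re-aimers show.
* IQR-based dispersion at n < ~20 per bin is noisy regardless of quartile
  convention; bins under 4 reports are only flagged, not suppressed.
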