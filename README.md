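# vmrloc

Analysis pipeline for cyclic visuomotor-rotation experiments that measure
how precisely people localize their unseen hand during *early* motor
adaptation, plus a seeded paradigm simulator with known ground truth.

In these paradigms, short adaptation cycles (cursor feedback rotated ±45°
relative to the hand) alternate with washout cycles (veridical feedback).
Every cycle of 2–4 reaches ends with a no-feedback reach after which the
hand is localized, either by moving a pointer to the felt hand position or
by a left/right (2AFC) judgment of a probe at ±3.33°, ±10°, or ±20° from
the true hand. Repeating the cycle many times yields enough localizations
to estimate, separately for adaptation and washout:

- **bias** — the shift of perceived hand position toward the rotated
  cursor: the mean sign-corrected angular error (pointer) or the point of
  subjective equivalence, PSE = −intercept/slope of a logistic psychometric
  fit (2AFC);
- **dispersion** (inverse precision) — the interquartile range of angular
  errors after per-target bias subtraction (pointer) or the just noticeable
  difference, JND = 2 ln 3 / slope (2AFC), with two-target designs pooled
  after aligning each target's curve at its own PSE.

The package covers the full path from raw 1 kHz hand paths to tidy
per-subject tables: kinematic event detection (onset = speed > 5 cm/s and
radius > 0.5 cm; offset = speed < 5 cm/s after the first peak), reach
features (direction at peak speed, extent, linearity index), the study's
screening rules (> 300 ms to the 10 cm radius, LI > 0.2, wrong-target,
premature/outlying pointer reports), aftereffect tables by preceding cycle
length, and an iterative variability-matching control that equates actual
hand-position variability between cycle types before re-estimating
localization dispersion. Inferential statistics are deliberately out of
scope; the exported CSVs feed any stats package.

## Worked example

```r
library(vmrloc)

cfg <- experiment_config("exp1", localization_method = "pointer")
ds  <- simulate_experiment(cfg, sim_params("exp1", seed = 1), n_subjects = 3)
run_pipeline(ds)
#> <vmr_report> exp1 / pointer
#>   reaches: 2268 (2164 kept)
#>   localization (pointer), across subjects:
#>     adaptation bias 1.61 deg (median 1.73), IQR 11.5 deg (median)
#>     baseline   bias 0.45 deg (median -0.138), IQR 6.46 deg (median)
#>     washout    bias 0.283 deg (median 0.038), IQR 5.61 deg (median)
#>   aftereffect by preceding cycle length: 2: 15.6, 3: 18.5, 4: 21.3 deg
#>   matching: 3/3 subjects matched, median removed 62 trials
```

Reading: perceived hand position is biased toward the rotated cursor in
adaptation cycles (≈ 1.6° vs ≈ 0.3° in washout) and markedly *less precise*
(error IQR ≈ 11.5° vs ≈ 5.6°); aftereffects grow with the number of
preceding rotated reaches (implicit learning); and the dispersion gap
survives the hand-position variability matching control. A 2AFC run
(`localization_method = "afc2"`) reports the same contrasts as PSE/JND.

Datasets round-trip through plain CSV/YAML (`write_dataset()` /
`read_dataset()`), and `inst/cli/vmrloc.R` exposes `simulate` and `run`
subcommands for shell use.

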