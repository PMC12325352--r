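# romocap

Marker-based motion-capture analysis of spinal and shoulder active range of
motion (ROM).

Clinicians and movement scientists assessing mobility — for example in
rehabilitation programs for people with obesity, where spinal and shoulder
mobility is often restricted — increasingly replace goniometry with
optoelectronic motion capture: reflective markers on anatomical landmarks,
tracked at 100 Hz by synchronized cameras. romocap turns those raw marker
trajectories into the quantities such studies report, and implements the
statistical workflow used to compare sessions and groups:

1. **I/O** — C3D, TRC, or a documented wide-CSV dialect, with vendor-label
   aliasing onto a canonical 14-marker upper-body schema (acromions, elbows,
   ASIS/PSIS pelvic landmarks, S1/L3/L1/T6/T1 spinous processes).
2. **Preprocessing** — linear gap interpolation and a zero-phase 5 Hz
   low-pass Butterworth filter (net 4th order, forward–backward).
3. **Kinematics** — a pelvis-anchored local frame (x along the ASIS line,
   y the upward pelvic-plane normal, z = x × y) and the full angle set:
   shoulder flexion/abduction/extension (SF/SA/SE) as planar projection
   angles from the neutral arm-down direction, shoulder-line inclination and
   rotation in laboratory and local frames (SIA/SIL, SRA/SRL), spinal
   segment lines (S1-L1 … T6-T1) and PELVIS/TRUNK/THORAX inclinations.
4. **Segmentation** — repetitions as prominence-filtered extrema of the
   task's primary angle; per repetition, ROM = max − min; task duration =
   last-repetition end − first-repetition start; pooling excludes the first
   repetition per set, averages the two sets, and pools sides only when a
   preliminary paired left/right test justifies it.
5. **Statistics** — Shapiro–Wilk and Levene checks, 2 × 2 mixed
   repeated-measures ANOVA (session × group interaction on PRE/POST),
   within-group RM-ANOVA across PRE/ACUTE/POST with Greenhouse–Geisser
   correction and Holm-adjusted paired post hocs, paired control-group
   tests, Cohen's d (paired `mean(diff)/sd(diff)`; pooled
   `(m₂−m₁)/√((s₁²+s₂²)/2)`) with left-closed bands at 0.20/0.50/0.80, and a
   per-repetition trend ("fatigue") analysis with per-subject percent change.
6. **Synthetic data** — a forward-kinematic trial and cohort generator with
   known ground truth (raised-cosine repetitions on a rigid-segment body
   model, Gaussian marker noise, configurable group/session effects and
   within-subject correlation), so the whole pipeline is testable without
   laboratory recordings.

## Worked example

Simulate one noisy shoulder-extension trial with a true mean ROM of
29.92° and recover it:

```r
library(romocap)

prof <- task_profile("backward_push", true_rom = 29.92)
prof
#> <task_profile> backward_push: ROM 29.92 deg (sd 3.00, trend +0.00/rep), 6 reps of 3.70 s (rest 0.93 s)

tr <- simulate_trial(prof, noise_sd = 2, seed = 7, side = "right")
md <- trial_metadata("WG01", "WG", "PRE", "backward_push", "right", 1)
analyze_trial(tr$trajectory, md)
#> <trial_result> WG01 PRE backward_push (right): 6 reps, pooled ROM 27.75 deg, duration 26.63 s

round(analyze_trial(tr$trajectory, md)$repetitions$rom, 2)
#> [1] 36.98 26.88 28.55 28.42 27.69 27.19
round(tr$truth$rom_per_rep, 2)
#> [1] 36.78 26.33 27.84 28.68 27.01 27.08
```

Despite 2 mm of marker noise, each detected repetition's ROM lands within a
few tenths of a degree of its ground truth; the pooled value (27.75°)
averages repetitions 2–6, excluding the habituation-biased first repetition.
Effect sizes from published-style summary statistics:

```r
cohens_d_summary(29.92, 15.67, 38.73, 17.70)
#> $d
#> [1] 0.5270449
#> $band
#> [1] "large"
```

A whole study — simulate a 21 + 21 cohort, run every stage, and write
`cohort.csv`, `stats.csv`, `summary.txt` and `provenance.json`:

```r
cfg <- validate_config(list(seed = 1, output_dir = "out"))
res <- run_pipeline(cfg)
subset(res$stats, term == "session:group" & parameter == "ROM")
```

A thin CLI wrapper is installed at `exec/romocap`
(`romocap run --config cfg.yaml`; exit codes 0/1/2 for ok / config error /
runtime error). The methods vignette (`vignettes/romocap-methods.Rmd`)
documents the measurement model, every tunable parameter and the design
decisions.

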