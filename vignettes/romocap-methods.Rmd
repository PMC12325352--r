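---
title: "Methods: from marker trajectories to ROM statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from marker trajectories to ROM statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

romocap quantifies active range of motion (ROM) of the spine and shoulders
from marker-based optoelectronic motion capture. This vignette documents the
processing model, its assumptions, the tunable parameters, and the design
decisions taken where the underlying methodology left choices open.

## The measurement model

A trial is a set of 3D trajectories (mm, 100 Hz by default) for a 14-marker
upper-body set: bilateral acromions (RACR/LACR) and elbows (RELB/LELB), the
four pelvic landmarks (RASIS/LASIS, RPSIS/LPSIS) and five spinous-process
markers (S1, L3, L1, T6, T1). The laboratory frame is right-handed with Y
vertical (up), Z anterior and X from the subject's left to right; all readers
convert into this convention, and all coordinates are held in millimetres.

Six motor tasks are analysed, each with a *primary angle* whose curve defines
the repetitions:

| task | primary angle | definition |
|---|---|---|
| frontal rise | SF | sagittal-plane elevation of the arm vector from the neutral downward direction, positive anterior |
| lateral rise | SA | frontal-plane elevation, positive away from the midline |
| backward push | SE | sagittal-plane elevation, positive posterior |
| lateral bending | SIL | angle between the shoulder line (RACR−LACR) and the local vertical y |
| twist | SRL | signed angle in the local transverse plane between the projected shoulder line and the local anterior axis z |
| anterior flexion | TRUNK | sagittal-plane angle of the S1→T1 vector from laboratory Y |

The remaining angles (SIA, SRA, the five spinal segment lines S1-L1 … T6-T1,
PELVIS, THORAX) are computed by the same machinery and exported alongside.

### The pelvis-anchored local frame

Angles labelled *local* are expressed in a per-sample frame anchored on the
pelvis so that pelvic motion is discounted: x is the RASIS−LASIS direction
re-orthogonalised against the pelvic-plane normal, y the upward normal of the
plane through RASIS, LASIS and the PSIS point, z = x × y.

Two wording ambiguities in the source methodology required decisions:

* A plane cannot be defined by the single RASIS→RPSIS vector. We fit the
  pelvic plane through RASIS, LASIS and the PSIS point — the midpoint of both
  PSIS markers when both are instrumented, the single PSIS otherwise. This
  uses every named landmark and degrades gracefully to one-sided
  instrumentation.
* SRL is described against a "coronal" plane, which is geometrically
  inconsistent with measuring rotation about the vertical axis; we interpret
  it as the local *transverse* (x–z) plane. This is flagged here deliberately:
  it is an interpretation, not a derivation.

Shoulder angles are planar projection angles from the neutral (−y) direction,
not 3D elevation angles: the three tasks are separable precisely because each
is measured in its own plane. Planar angles are signed in (−180°, 180°];
line-vs-axis angles are unsigned in [0°, 180°]. When the projection of a
vector onto its measurement plane drops below 1% of the vector's norm the
angle is indeterminate; such samples are flagged `NA` and excluded from
extrema detection.

## Preprocessing

Gap interpolation is coordinate-wise linear between the flanking valid
samples (`interpolate_gaps()`), refusing gaps that touch a trial boundary or
exceed `max_gap` (default 20 samples = 0.2 s at 100 Hz — conservative, since
no gap-filling limit is documented for the original recordings; longer gaps
are an error rather than silently filled).

Filtering is a 5 Hz low-pass Butterworth (`filter_spec()`). Only the cutoff
is prescribed by the methodology; order and phase handling are our decision:
a **zero-phase forward–backward pass of a half-order design** (net order 4),
the de-facto standard in movement analysis, so extrema positions are not
lagged. Both order and single-pass mode are configurable. Edge handling uses
odd (point-symmetric) reflective padding of 3 × order samples with
steady-state initial conditions, which makes the DC gain exact to machine
precision and results bit-reproducible. No cutoff-frequency correction is
applied for the double pass; the passband error this leaves at 1 Hz is below
0.2%.

## Repetition segmentation

Repetitions are found on the primary-angle curve as local maxima whose
topographic prominence exceeds `min_prominence_frac` (default 0.2) of the
curve's global amplitude; each retained maximum with its flanking minima is
one repetition, and ROM is max − min within it. Boundaries prefer the nearest
local minimum below 10% of the global amplitude — the rest plateaus between
repetitions — falling back to the lowest point of the valley. Curves whose
excursions run *downward* from the resting value (e.g. a left-side bend
decreases the shoulder-line inclination) are auto-oriented by comparing the
median-to-extreme distances before detection. A detected count different from
the expected six is recorded as a warning, not a failure: real recordings may
contain extra or aborted cycles, and the deviation is kept in the cohort
table.

Task duration is (end of last repetition − start of first repetition) /
sample rate. Pooling follows the study design: the mean over repetitions 2..n
per set (the first repetition of each set is excluded against initial
measurement bias — we apply the exclusion *per set*, the conservative reading
of "per side" with two sets per side; `exclude_first = FALSE` disables it),
then the mean of the two sets, then the mean of the two sides — the latter
only when the preliminary paired left/right comparison (`side_comparison()`)
found no systematic asymmetry, otherwise sides are kept separate.

## Statistics

On the participant-level cohort table the workflow mirrors a standard
pre/post controlled design with one treated (WG: PRE/ACUTE/POST) and one
control group (CG: PRE/POST):

* Shapiro–Wilk per group × session cell and Levene across groups
  (`check_assumptions()`); degenerate cells are skipped and logged.
* 2 × 2 mixed-design ANOVA on PRE/POST with group as the between factor
  (`mixed_rm_anova()`, via `stats::aov` with an `Error(participant)`
  stratum); the session × group interaction is the headline test.
* Within the treated group, one-way repeated-measures ANOVA across all three
  sessions (`rm_anova_within()`), with a Greenhouse–Geisser-corrected p
  reported alongside the uncorrected one (the source is silent on sphericity;
  with three levels the correction is cheap insurance). Post hocs are paired
  t-tests with Holm step-down adjustment (`holm_posthoc()`, via
  `stats::p.adjust`).
* For the control group, paired PRE–POST t-tests.
* Cohen's d: paired contrasts use mean(diff)/SD(diff) — consistent with the
  printed effect sizes, which are not recomputable from summary means/SDs
  alone — and the pooled-variance variant
  (m₂ − m₁)/√((s₁² + s₂²)/2) is also available (`cohens_d_summary()`).
  Bands are left-closed: < 0.20 small, 0.20–0.50 moderate, 0.50–0.80 large,
  ≥ 0.80 very large.
* Fatigue/repetition-trend analysis (`fatigue_analysis()`): RM-ANOVA across
  the ordered repetitions plus a first-vs-last paired post hoc. Percent
  change is computed **per participant** as 100·(last − first)/first and then
  averaged; the ratio-of-group-means variant is reported alongside but the
  published per-session percent changes are consistent only with a
  per-subject computation, so that is the default. α = 0.05 throughout;
  no multiple-testing control is applied across tasks (correction happens
  only within post hoc families).

## The synthetic-data generator

Because the study's recordings are not required for testing, every stage is
validated against forward-kinematic synthetic trials with known ground truth
(`simulate_trial()`, `simulate_cohort()`). The task's primary angle follows,
per repetition r,

θ_r(t) = (ROM_r/2)·(1 − cos(2πt/rep_period)),  ROM_r = true_rom + trend·(r−1) + N(0, rep_rom_sd²),

with rest plateaus between repetitions so that extrema are isolated, and
markers placed by rigid-segment forward kinematics on a body model with
realistic dimensions (inter-ASIS 240 mm, upper arm 300 mm, S1→T1 470 mm).
Soft-tissue artifact is modelled only as i.i.d. Gaussian marker noise
(default 1 mm SD per coordinate, a realistic figure for optoelectronic
capture including small soft-tissue motion); no richer artifact model is
available to emulate. A secondary degree of freedom (`pelvis_follow`) can
rotate the pelvis with a fraction of the driving angle to probe angle
cross-talk; it is off by default.

Cohort simulation draws each participant's true ROM and task duration per
session from the configured group/session normal distributions — the
defaults in `cohort_reference()` are the published group means/SDs for the
primary parameter of each task — with compound-symmetric within-subject
correlation across sessions (default ρ = 0.8, a typical test–retest figure
for instrumented ROM). Two floors keep draws physical: ROM ≥ 5° and duration
≥ 5 s; the per-repetition SD is capped at 10% of the participant's ROM so
that small movers do not get degenerate repetition profiles. Inter-repetition
deviations are assumed i.i.d.; the real correlation structure is unknown,
and this assumption is the main reason cohort-level results should be read
as *consistency* checks, not as re-measurements of the study. The repetition
period defaults derive from the published mean task durations via
duration = n·p + (n−1)·p/4 (rest plateau = a quarter period).

Seeding: one integer master seed; per-trial seeds follow the documented
counter scheme `(seed + 97·counter) mod (2³¹ − 1)` (`derive_seed()`), so
cohorts are bit-reproducible and trials are independently re-creatable.

### What passing tests do and do not show

The generator produces smooth, single-frequency, rigid-body movement with
white marker noise. Passing recovery tests therefore demonstrates that the
geometry, filtering, segmentation and statistics are implemented correctly
and are robust to measurement noise of realistic magnitude — not that the
pipeline is robust to skin-marker artifact, mislabelled markers, aborted
repetitions or non-stationary movement speed, none of which the generator
emulates.

## Problem sizes used in the checks

The packaged verification suite uses sizes chosen to exercise the claims
meaningfully on a single CPU: 1000 random configurations for the
angle-oracle comparison (tolerance 10⁻⁹ deg); noiseless and 2 mm-noise
recovery over 100 trials per task (tolerances 10⁻³ deg per repetition,
0.5°/2° pooled, 2 samples duration); 1000 null replicates for the type-I
rates of both ANOVAs (band 0.035–0.065 at α = 0.05); and 500 replicates of a
21 + 21 cohort — simulated at the published shoulder-extension means/SDs
with ρ = 0.8, one set of six repetitions per participant-session and a 1 s
repetition period — for session × group interaction detection, with 100
equalized-effect replicates as the negative control. The shortened
repetition period keeps the simulation compact; detection power is governed
by the participant-level variance structure, not trial length.

## Known limitations

* Shoulder angles are projection angles; they are not comparable to
  goniometric 3D elevation in oblique planes.
* Whether SF/SA should be computed in the local or the laboratory frame is
  not documented for the source protocol ("relative to the torso"); the
  default is the local frame, switchable via `use_frame`.
* The C3D codec covers Intel-format floating-point point data only — the
  subset the package itself writes; integer-scaled or DEC/MIPS files are
  rejected rather than misread.
* Listwise deletion for incomplete sessions; no imputation.
* No velocity/acceleration metrics, no inverse dynamics, no Euler-sequence
  joint decomposition.
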