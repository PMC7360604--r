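---
title: "Models and methods behind stressreg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind stressreg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

stressreg implements an end-to-end analysis pipeline for mixed-design
psychophysiology studies of acute stress and cognitive emotion regulation:
a synthetic-study generator, a pupillometry preprocessing chain ending in
AUCg (area under the curve with respect to ground), salivary endocrine and
affect summaries, and a repeated-measures ANOVA engine. This vignette
explains the models, the tunable parameters and their defaults, the
numerical choices, and what the synthetic data can and cannot establish.

## The study world

The generator emulates a 2 × 3 between-subjects design — stress condition
(psychosocial stressor vs. non-stressful control) crossed with sex-hormone
group (males, free-cycling females in the luteal phase, females taking oral
contraceptives) — with five within-subject emotion regulation conditions
(view neutral, view negative, intensify, reappraisal, distraction), ten
trials each. Each trial follows the paradigm timing: 750 ms instructional
cue, 2,500 ms fixation, 5,000 ms picture, three 5,000 ms rating screens and
a 2,000 ms inter-trial interval. Binocular pupil diameter is sampled at
30 Hz; saliva (cortisol in nmol/l, alpha-amylase in U/l) is sampled at
baseline, +2, +15 and +45 min after stressor offset; the Differential
Affect Scale (DAS) at baseline, +2 and +45.

### Pupil model

Each trial's noise-free diameter is

$$x(t) = \text{tonic} + a\,\sigma\!\left(\tfrac{t-1000}{250}\right)
              + e\,\sigma\!\left(\tfrac{t-1500}{250}\right),$$

with $t$ in ms relative to picture onset and $\sigma$ the logistic
function. The first component models emotional arousal: it rises from
picture onset and plateaus by ~2 s, so the 2–5 s AUCg window sits on the
plateau. The second models cognitive regulatory effort; its onset is
delayed 500 ms because the regulation instruction takes effect late. The
exact ramp shapes are not constrained by any published description — the
logistic was chosen once for smoothness and a closed-form integral, and the
parameter-recovery tests integrate exactly this curve as their oracle.
Default amplitudes (mm): arousal 0.05 / 0.30 / 0.40 / 0.30 / 0.15 and
effort 0 / 0 / 0.25 / 0.20 / 0.15 across the five conditions in canonical
order, i.e. dilation ordered negative > neutral, and intensify/reappraisal
above view-negative once effort is added — the qualitative pattern the
analysis stage is expected to recover. Stressed males get +0.15 mm of
reappraisal effort, the pupil-side analogue of their rating shift. Tonic
level is 4.5 ± 0.3 mm between participants, ±0.1 mm between trials, and
the clean signal is clamped to a physiological band (1.6–8.9 mm) before
artifacts are injected.

Artifacts, all configurable: blinks as missing-sample runs at 0.10/s with
lognormal duration (median 120 ms, σ = 0.5 on the log scale) — chosen so a
realistic share of blinks falls on either side of the 100 ms interpolation
limit; single-eye dropouts (0.05/s, 100 ms) exercising the binocular
fallback; isolated ±1.5 mm speed spikes (0.02/s); a rare 3-sample
out-of-range run (1% of trials); and Gaussian sample noise (SD 0.05 mm).
`no_artifact_params()` zeroes every artifact source but keeps the sample
noise: on a noise-free smooth trace the dilation-speed statistics are
degenerate (median and MAD near zero) and the genuine ramp itself would be
flagged, so "artifact-free" deliberately means "clean but measured".

### Saliva, affect and ratings

Each participant draws one baseline-to-peak delta per analyte from their
stress × hormone cell's mean and SD. The stress-group cortisol delta means
default to the published group values (MALE 13.96, FELU 4.55, FEOC 4.48
nmol/l; controls slightly negative), the SDs to the published SEMs scaled
to ~20 participants per cell (the real per-cell ns are not printed; 118/6
≈ 20). A positive delta produces a peaked time course — cortisol peaking
at +15 min (the HPA axis is slow), alpha-amylase at +2 (sympathetic
activity is fast); a negative delta produces a monotone decline. Either
way the post-baseline maximum minus baseline equals the drawn delta, so
the delta-summary stage recovers the generating means by construction; the
only biases left are the measurement noise acting through the max (small)
and the positivity floor, which truncates large negative declines in the
control cells (physiological — concentrations cannot go negative) and
shifts control-cell recoveries upward by up to ~1 nmol/l. DAS negative
factors follow the same delta logic on a 1–5 scale with the spike at +2.

Ratings are Gaussian draws around per-condition means (arousal ordered
intensify > view negative > reappraisal/distraction > view neutral,
valence reversed), plus a participant-level shift (SD 0.5) and trial noise
(SD 1.2), then rounded and clamped to their scales. Stressed males receive
the configured reappraisal shifts (arousal −0.8, valence +0.8, success
+0.8) — approximately a 0.8-SD effect, matching the size of effect the
design is meant to detect. Rounding leaves cell means essentially unbiased;
clamping matters only for means within ~2 SD of a scale end.

All randomness flows from one seed through per-participant, per-table
sub-streams; the clean pupil signal and the artifact process use separate
streams, so raising artifact rates never changes the underlying signal —
which is what makes the "artifacts never increase the number of valid
trials" property testable.

## Pupil preprocessing

Order of operations: average eyes → FIR smoothing → event-locked
segmentation → range filter → dilation-speed filter → gap handling →
baseline correction → AUCg → per-condition aggregation. The published
description lists these steps but does not fully order them; smoothing is
placed before segmentation to avoid filter edge effects at trial
boundaries, and the smoother splits at missing samples and at time jumps
larger than 1.5 sample periods so it never bridges blinks or inter-trial
gaps. Whether the original routine smoothed before or after artifact
removal is unknown; the chosen order at least prevents the smoother from
smearing spike artifacts into neighbouring samples *after* they have been
flagged (spikes are flagged on the smoothed signal, which attenuates but
does not hide a 1.5 mm single-sample excursion).

- **Binocular averaging**: elementwise mean; when one eye is missing the
  other is used (configurable strict mode requires both). This preserves
  data at the cost of a small variance inhomogeneity.
- **Smoothing**: linear-phase windowed-sinc (Hamming) low-pass, 6 Hz
  cutoff, 31 taps, applied symmetrically about each sample (zero phase)
  with edge weights renormalised to keep unit DC gain. Only "FIR at 6 Hz"
  is specified; tap count trades stopband depth against edge span.
- **Range filter**: any sample outside 1.5–9 mm (inclusive bounds kept)
  discards the trial.
- **Dilation-speed filter**: per-sample speed is the larger absolute slope
  towards the two adjacent non-missing neighbours; threshold =
  median + k·MAD with the *raw* MAD (no 1.4826 consistency constant) and
  k = 16, the midpoint of the admissible 6–30 range; k is exposed and
  bounded. If MAD = 0 (constant trace) nothing is flagged. Thresholds are
  per trial ("individually"); a pooled per-participant mode is available.
- **Gap handling**: gap duration = run length × sample period; gaps
  strictly longer than 100 ms (major blinks), and leading/trailing gaps,
  discard the trial; others are linearly interpolated. A 3-sample gap at
  30 Hz (100 ms) is kept; 4 samples is not.
- **Baseline correction**: mean over [−300, 0) ms before picture onset,
  subtracted from the whole trace (idempotent by construction).
- **AUCg**: signed trapezoidal integral of the corrected dilation over
  2–5 s after picture onset, in mm·s, "ground" being the post-correction
  zero line; negative dilation subtracts. When no sample falls exactly on
  a window edge the edge value is interpolated, so the integral always
  covers exactly 3 s. The generator quantises event onsets to the sample
  grid (fixation padded to 2,516.7 ms, ITI to 2,016.7 ms) so that picture
  onset, the baseline edge and both AUCg edges are exact samples — 750,
  2,500 and 5,000 ms are not commensurate with a 33.3 ms sample period,
  and something has to give; the events table keeps the nominal timings.
- **Aggregation**: per-condition mean over valid trials; a condition cell
  needs at least 5 of 10 valid trials, else it is missing (the original
  report only says eight participants were lost to technical failure — 5
  is a conventional half). The log transform used for AUCg statistics is
  ln(x + shift) with shift = 1 − min(x) when any value is non-positive
  (AUCg can legitimately be negative); the shift is recorded on the output.

## Statistics

`mixed_anova()` implements the classical univariate split-plot
decomposition with SPSS-style conventions, because that is the environment
the published analysis used: sum-to-zero coding with marginal (Type III)
sums of squares, so unbalanced between-subject cells are handled the way
GLM repeated measures does. The between stratum is the ANOVA of
√k-scaled participant means; the within stratum projects each
participant's k within-level scores onto an orthonormal contrast basis and
accumulates Type III SS per contrast variate. Greenhouse–Geisser epsilon
comes from the pooled within-cell error covariance of the contrast
variates (clipped to [1/(k−1), 1]; exactly 1 when k = 2), Mauchly's W from
the same matrix with the first-order chi-square approximation. Partial
η² = SS_effect / (SS_effect + SS_error). By default GG-corrected dfs and
p-values are *reported* (column `p_reported`) only when Mauchly rejects at
0.05, matching the published reporting rule; `gg_policy = "always"` is
available, and the uncorrected and corrected values are always both in the
table. Participants missing a within level are dropped listwise; between
factors that end up with one level (e.g. a control-only subset) are
dropped from the model.

On balanced designs the engine agrees with `stats::aov` split-plot output
to 1e-8; on single-group designs it agrees with an independent reference
implementation (pingouin) for SS, F, ε and W — the Mauchly *p* differs in
the third decimal because pingouin adds a higher-order term to the
chi-square approximation.

Post-hoc contrasts are Welch t tests between groups (the published
fractional dfs imply unequal-variance tests) and paired t tests within
conditions, with p-values multiplied by the family size and capped at 1;
family composition is caller-supplied because published family sizes are
not stated. Degenerate contrasts (identical constant cells) return t = 0,
p = 1 rather than erroring. `welch_t_from_summary()` computes the same t
from published mean/SEM cells — the forms coincide, which is what lets the
printed table's t statistics be reproduced without raw data. Normality
checks use the KS statistic with Monte-Carlo (Lilliefors-style) null
distribution — the naive KS p-value is far too conservative with estimated
parameters — under a fixed internal seed so runs are reproducible; Levene's
test uses centre = mean. `delta_response()` takes max(post) − baseline
(signed), with a fixed-timepoint option.

## Scope of what a green test establishes

The synthetic world reproduces the design, timing, artifact structure and
effect topology of a real study, not its physiology: no luminance or gaze
confounds, no assay chemistry, no circadian drift, no correlation between
endocrine response and pupil/rating effects (each table draws its own
participant effects), and trial order is blocked-random rather than the
exact published sequence constraints. Recovery and type-I tests therefore
validate the *pipeline* — that the estimators recover what generated the
data and reject at nominal rates under the null — and the published
real-data F, η² and correlation values are deliberately not targets; only
the summary-statistic t tests, which depend on printed numbers alone, are
reproduced numerically. Two of the five printed t values (FEOC cortisol,
MALE alpha-amylase) do not reconcile with the printed means/SEMs at
two-decimal precision and are documented as un-targeted; the likeliest
explanation is rounding of the published cells.

## Known limitations

- The crossed-random-effects (stimulus × participant) mixed model used as
  a published robustness check is out of scope; `difference_scores()` plus
  `mixed_anova()` covers the difference-score robustness route instead.
- Control-cell delta recovery is biased upward by the positivity floor
  (documented above); stress-cell recovery is unbiased to within ~0.1
  nmol/l.
- The split-plot engine supports one within-subject factor (all analyses
  here need exactly one); factorial within designs would need a second
  projection layer.
- With heavy artifact rates and `min_valid = 5`, small simulated studies
  can lose whole participants from the pupil ANOVA; the pipeline records
  unestimable models in the run report rather than failing the run.
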