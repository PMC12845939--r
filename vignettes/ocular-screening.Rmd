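---
title: "Methods: ocular biometric gating and baseline-relative depression-pattern screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ocular screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ocugate)
```

`ocugate` is a tested realisation of a two-module pre-drive screening
pipeline: iris-code identification followed by pupillometric / oculomotor
screening for a depressive physiological response pattern, with a four-way
access decision fused from the two outcomes. No real recordings ship with the
package; everything runs on a seeded synthetic-data generator whose defaults
encode the study conditions the pipeline is meant to emulate. This vignette
explains the models, the parameters that matter, what the generator does and
does not emulate, and the numerical choices in the implementation.

## 1. The identity module

### Segmentation

Pupil and limbus circles are located with a deterministic
integro-differential operator: the fitted circle maximises the Gaussian-blurred
radial derivative of the circular mean intensity,
$\max_{(c_x, c_y, r)} \left| G_\sigma * \tfrac{\partial}{\partial r}
\oint I \, ds \right|$. The pupil is fit first (dark disc), then the limbus,
constrained to a concentric, strictly larger circle. After the integer grid
search the radius is refined on a 0.25 px grid with a parabolic peak
interpolation; on the synthetic renders this brings the radius error to about
0.1 px, which matters because a radius bias shifts the whole normalised
texture radially. A learned segmenter for real imagery can be swapped in: the
downstream code only consumes a `boundary_fit`.

A flat or featureless image (no dark disc, edge response below 0.02
intensity/px) is a detection error, not a degenerate fit.

### Normalisation and coding

The annulus is resampled by the homogeneous rubber-sheet model onto a fixed
`n_radial x n_angular` pseudo-polar grid (`rho` at mid-point offsets in
(0,1), `theta` uniform in `[0, 2*pi)`, bilinear interpolation). Each radial
row is then band-pass filtered along the (periodic) angular axis with a
log-Gabor transfer function $H(f) = \exp(-\log^2(f/f_0) / (2\log^2\sigma_r))$
(centre frequency `f0 = max(2, n_angular/8)` cycles, bandwidth ratio 0.5,
zero DC response), and every position is quantised to two bits by phase
quadrant. The default grids are 16 x 16 (512 bits) and 16 x 32 (1024 bits);
the layout (16 radial rows, 2 phase bits per position) is a design choice —
the bit budget alone does not determine it.

Matching uses the fractional Hamming distance minimised over circular
angular shifts of up to ±4 positions (one position = 2 bits), the standard
tolerance for in-plane rotation between acquisitions; acceptance threshold
0.32 (configurable). No occlusion mask is carried: the synthetic eyes have no
lids or lashes. The interface reserves the slot.

One subtlety: when two *samples* of an identity are compared (rather than a
sample against its enrolled template), their relative rotation can reach
twice the per-sample jitter. `score_gallery()` therefore defaults its shift
search to twice the gallery's rotation jitter, while probe-versus-template
identification keeps ±4. Without this, a quarter of genuine pairs under ±4
jitter would be unmatchable by construction.

### Error rates

`evaluate_biometrics()` computes FAR (impostor scores at or below the
threshold), FRR (genuine scores above it), GAR = 1 − FRR on a threshold grid
(default step 0.002), and the EER by linear interpolation on the grid segment
where FAR − FRR changes sign. FAR is non-decreasing and FRR non-increasing in
the threshold by construction; both facts are asserted as test invariants.

## 2. The screening module

### Features

Per stimulus block (5 s neutral baseline, 8 s stimulus, 5 s rest) the
extractor computes, per the glossary of event-related pupillometry:

* **PDA** (% of baseline): signed peak deflection of the pupil diameter in
  `[onset, onset + 10 s)` relative to the baseline mean `B` over the last
  3 s before onset. The *signed extremum* (largest |deviation|) rather than a
  literal maximum — a blunted or constricting response must come out
  negative, not be clipped at zero.
* **CL** (ms): start of the first excursion of the smoothed diameter above
  `B + 1 SD(baseline)` sustained for at least 300 ms; censored at the window
  end. The debounce suppresses noise-floor crossings. Note the structural
  bias of any causal threshold rule: with the response kernel below, the
  signal reaches ~1% of its peak only ~335 ms after onset, so under
  measurement noise the crossing trails the true onset by roughly the rise
  time to threshold (hundreds of ms). CL is therefore a *relative* marker —
  comparable within a person against their own baseline, which is exactly how
  the screening rule uses it — not an absolute onset estimate. The tests
  assert exact onset recovery only in the noise-free limit.
* **PDV** (%/s): maximum first derivative of the percent-change signal.
* **FD / SV / SA**: mean fixation duration, mean saccade peak velocity,
  mean saccade amplitude over events whose midpoint lies in the stimulus
  window, from an I-VT detector (velocity threshold 30 deg/s, minimum
  fixation 50 ms, minimum saccade 10 ms; sub-threshold fragments folded
  back). These are standard I-VT values; the underlying method names no
  algorithm, so the detector choice is a recorded design decision.
* **GDE** (bits): Shannon entropy of valid gaze samples binned on an 8 x 8
  equal-area grid over the display extent (default ±16° x ±10°); bounded by
  `[0, 6]` bits.
* **EMA**: `|dL - dR| / max(0.05, (dL + dR)/2)` on the per-eye absolute
  dilations in mm — a declared construction, since no definition of the
  asymmetry index is given by the source method; missing (not an error) for
  single-eye sessions.

Preprocessing: out-of-range (outside 1.5–9 mm) and invalid samples are
treated as blinks; missing runs up to 500 ms are linearly interpolated,
longer runs stay invalid; the pupil is smoothed with a 100 ms moving average
and gaze velocity comes from central differences with 20 ms smoothing.

### Baseline profiles and the 2-SD rule

Every participant contributes at least three reference sessions covering at
least two states (rested / tired / stressed). Per feature, the baseline is
the mean and SD of the session-level feature means, with the SD floored at
`max(0.05 |mean|, eps_f)` (per-feature `eps_f`, e.g. 0.5 percentage points
for PDA) so that over-consistent references cannot inflate z-scores without
bound. Pupil features (PDA, PDV) are profiled **per valence**: dilation to
negative news and blunting to positive news are different baselines, and
pooling them would make every normal participant look deviant in both gated
directions. Valence-neutral features (FD, SV, SA, GDE, EMA, CL) are profiled
across all stimuli.

Screening z-scores are sign-gated by a direction table (negative news: PDA+,
PDV+, FD+; positive news: PDA−, PDV−, FD+), a stimulus is flagged when at
least 2 of the 3 core features deviate by `z >= 2` (inclusive, "at least 2
SD"; the aggregation mode is configurable between any/majority/all because
the source phrasing is ambiguous — majority is the default), and a
participant is labelled depressive-pattern when at least 3 of 6 stimuli are
flagged. Monotonicity (raising a gated deviation never un-flags; raising the
threshold never flags more) is asserted as a property test.

### The logistic model and the sequence classifier

`fit_logistic()` is a plain maximum-likelihood logistic regression (IRLS via
`glm`) with likelihood-ratio chi-square and Nagelkerke R² diagnostics, a
perfect-separation guard that errors instead of returning unstable
coefficients, and an option to freeze externally published slopes
(0.085 / −0.11 / 0.007 for PDA to negative news, pupil response to positive
news, and fixation duration) while fitting only the intercept.

The sequence classifier operates on 2-channel per-stimulus windows (13 s:
last 3 s of baseline, 8 s stimulus, 2 s rest) of pupil percent-change and
gaze speed. It is a random convolutional kernel transform: a seeded bank of
random 1-D kernels (9 taps, dyadic dilations, mean-centred Gaussian weights)
is applied per channel; each kernel contributes a max-pooled and a
proportion-of-positive feature; a ridge-penalised logistic readout
(`glmnet`, alpha 0) is trained on the 70 % participant split with the
penalty chosen by validation-split log-loss — the analogue of early
stopping — and evaluated on the test split. Splits are at participant level
to prevent stimulus-level leakage. Per-stimulus probabilities aggregate per
participant by the mean. Random-kernel transforms are an established,
fast, and seed-deterministic approach for time-series classification; a
conv-recurrent network could be plugged behind the same
`train_seq_classifier()` surface without touching callers.

## 3. The synthetic-data generator

The generator is first-class, tested code; its defaults *are* the study
conditions.

* **Cohort**: 242 participants, 81 (33.5 %) carrying the depressive response
  pattern. Group feature distributions (mean/SD) for the four reported
  contrasts: PDA to negative news 18.4 (6.7) vs 27.9 (8.3) %; PDA to positive
  news 6.2 (4.1) vs −1.3 (5.0) %; FD 280 (40) vs 345 (52) ms; SV 320 (45) vs
  276 (51) deg/s.
* **Severity factor**: deviations toward the depressive direction are
  equicorrelated across the four features with `rho = 0.25` via a one-factor
  construction (`u_j = sqrt(rho) g + sqrt(1-rho) e_j`, signs aligned to the
  effect directions). The alignment matters: applying the equicorrelation on
  the raw feature scale with mixed effect signs would *increase* the
  four-feature Mahalanobis separation far above what the reported
  discrimination (AUC ≈ 0.94) implies, whereas a shared severity factor
  reproduces it. `rho` is configurable.
* **Within-participant scatter**: per-stimulus values scatter around the
  participant latent with SD equal to 30 % of the between-participant SD, and
  reference sessions additionally carry a session-level state wobble of the
  same scale. The 30 % fraction is a declared guess — the source reports no
  within-person variability — and is a single `within_frac` parameter.
* **Baselines vs screening**: one trait deviation underlies both the
  reference latents (centred on the control distribution — the person's own
  neutral reactivity) and the screening latents (centred on the group
  distribution). Depression therefore shifts the screening session *relative
  to the individual baseline*, which is the signal the rule screens for.
* **Ancillary features**: PDV is derived from the valence-specific PDA latent
  at 1.7 %/s per % (the peak slope of the unit response kernel at the default
  shape) plus its own noise; CL, SA (via the inverse main sequence), GDE and
  EMA get realistic but group-nondiscriminative distributions, since no group
  contrasts are reported for them.
* **Pupil traces**: `d(t) = B (1 + sum_b (A_b/100) h(t - onset_b - lambda)) +
  noise`, with the gamma-family kernel
  `h(t) = (t/t_max)^n exp(n (1 - t/t_max))`, `n = 10.1`, `t_max = 930` ms —
  the standard pupillometry impulse-response parameters — normalised to a
  unit peak at exactly `t_max`. Blinks are Poisson missing runs.
* **Gaze traces**: alternating fixations (Gaussian positional noise) and
  saccades with raised-cosine displacement profiles whose peak velocity
  follows the main sequence `v_peak = v_max (1 - e^{-A/a_0})`
  (`v_max = 500` deg/s, `a_0 = 12` deg).
* **Eye images**: concentric pupil/limbus circles at known ground truth
  (pupil radius `base * (1 + dilation)`, dilation 0.10–0.40), an
  identity-seeded band-limited texture painted as a function of angle and
  *normalised* radius (hence dilation-invariant by construction), plus
  rotation jitter, centre jitter and pixel noise. Radial texture resolution
  is deliberately coarse (8 rows) because the annulus is only ~30 px wide;
  finer radial texture aliases at pixel scale and artificially degrades
  dilation invariance.
* **Rater matrices**: 186 items x 3 raters, 1–9 integer scales for valence
  and arousal; item truths and rater noise are separate dials, so the
  population single-measure ICC is approximately
  `sd_item^2 / (sd_item^2 + sd_rater^2)` (rounding attenuates slightly).

All randomness flows from one root seed through named substreams
(cohort / trace / iris / ratings / splits), so regenerating one input never
disturbs another.

**What the generator does not emulate** — and hence what green tests do *not*
show about real data: luminance and light-reflex effects (illumination is
constant by protocol), head pose and camera geometry, eyelid/lash occlusion
and mascara, habituation across stimuli, diurnal or medication effects on
pupil dynamics, demographic structure, and any correlation between identity
(iris) and clinical state. The group contrasts are taken at face value from
printed summary statistics; passing tests demonstrate that the *machinery*
(features, rule, models, metrics) behaves correctly under those conditions,
not that the screening would achieve comparable accuracy in the field.

## 4. Numerical and procedural choices

* Windows are half-open `[start, end)`; time is in ms on the trace grid.
* The baseline uses the last 3 s of the 5 s baseline phase (first 2 s are
  settling); the PDA search window runs 10 s from onset to catch late peaks.
* Threshold comparisons are inclusive (`p >= t`, `z >= k`), matching the
  "at least" phrasing of the decision rules.
* EER interpolation is linear on the first sign-change segment of FAR − FRR.
* ICC is fixed to the two-way random-effects, absolute-agreement,
  single-measure form ICC(2,1), computed from the two-way mean squares; the
  choice is recorded since the source names only "ICC".
* Corpus exclusions run before valence labelling: rater range strictly
  greater than 2 scale points on either scale, then arousal means at the
  inclusive extremes (≤ 2, ≥ 8); valence means in the open interval
  (3.5, 6.5) are excluded as neutral.
* `classify_rule` errors when fewer stimuli than the decision threshold are
  supplied; `identify` breaks distance ties by lowest gallery index;
  metrics with zero denominators are `NA`, never exceptions.
* The gatekeeper never grants on a rejected identity, and screening is
  recorded as not-run when identification fails (the screening module only
  executes after a successful identification).
* Problem sizes in the test-suite and acceptance protocols (e.g. 100
  identities x 5 samples with 10^4 impostor pairs over 5 seeds for the EER;
  25 seeds of the default 242-participant cohort for the screening AUC;
  an 80-participant cohort and 10 shuffle seeds for the label-permutation
  null of the sequence classifier) were chosen as the smallest sizes at which
  the quantities of interest are statistically stable.

## 5. Known limitations

* The depressive-pattern label is a physiological screening flag. Fatigue,
  stress, medication and arousal disorders can mimic parts of the pattern;
  the multi-state baseline mitigates but does not remove this.
* CL from threshold crossing is late-biased by the kernel rise time (see
  above); absolute latency comparisons across studies would need model-based
  onset estimation.
* The integro-differential segmenter assumes clean, near-circular,
  high-contrast boundaries; real near-infrared imagery needs a trained
  segmenter behind the same interface.
* The logistic model's remaining predictors (SV, GDE) have no published
  slopes; when slopes are frozen, only the three published coefficients are
  used.
* Printed dataset-bound figures of the source study (per-configuration
  GAR/FAR/FRR, group t and d values, Nagelkerke R², threshold-specific
  sensitivities) depend on private data and are not reproduction targets;
  the corresponding machinery is validated against oracles and property
  tests instead.
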