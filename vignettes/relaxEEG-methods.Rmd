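---
title: "Estimating a relaxation state from prefrontal EEG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating a relaxation state from prefrontal EEG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(relaxEEG)
```

## The problem

relaxEEG estimates a self-reported relaxation state — the *R-state*, a 1-9
scale in which values above 5 indicate relaxation — from three-channel
prefrontal EEG (FP1, FPZ, FP2 in the 10-20 system, 256 Hz) recorded around
short relaxing viewings. A session has a fixed layout: a 2-minute eyes-open
rest, a 90-199 s viewing, and a second 2-minute rest. Two complementary
analyses are supported:

1. **Group statistics** — which spectral features change when people watch a
   relaxing scene, tested per feature across paired *viewing contrasts*
   (`pre_end`, `pre_post`, `begin_end`), with a cross-participant
   consistency check.
2. **Regression** — predicting the per-viewing R-state label from spectral
   features of the final seconds of the viewing, evaluated with
   leave-one-subject-out (LOSO) cross-validation, with a two-level stacking
   ensemble on top.

Because raw human recordings for this paradigm are not publicly deposited,
the package ships a synthetic session generator that reproduces the study's
structure (26 participants x 3 viewings, 71 of 78 segments usable) and
provides ground truth for every downstream stage.

## The synthetic generator

Every feature in the bank is a spectral or variance functional, so the
minimal signal model that exercises all of them is a sum of band-limited
Gaussian processes over a pink-noise floor. Per channel,

$$x(t) \;=\; \sum_b \exp\!\big(\tfrac12 \log P_b(r(t))\big)\, u_b(t) \;+\; p(t),$$

where \(u_b\) is unit-variance noise confined to band \(b\), \(p\) is
\(1/f\) noise over 0.5-50 Hz with total power `noiseFloor` times the summed
reference band power, and the log band power responds linearly to the
latent relaxation \(r(t)\):

$$\log P_b(r) = \beta_b + \textit{slope}_b \,(r - 5).$$

The latent trajectory \(r(t)\) sits at a baseline of 3 during the pre-rest,
ramps linearly to the segment's latent R-state over the first half of the
viewing, and stays on that plateau through the post-rest. This guarantees
that `begin` differs from `end` and `pre` differs from `post`, the
qualitative pattern the statistics stage is designed to detect. The
hemispheric response applies `asymmetryResponse` to the FP2-FP1 alpha
log-power difference (half added on the right, half subtracted on the
left), so a positive slope makes the differential asymmetry of the alpha
differential entropy (DASM-alpha) *decrease* with relaxation.

Sessions are synthesized as three piecewise-stationary intervals (pre-rest,
ramp, plateau-plus-post) joined by half-second equal-power cosine
crossfades; adjacent intervals share the same spectrum at the seam, so the
joint process keeps its variance and has no discontinuity to ring on.
Only ramp-modulated bands need per-band synthesis, which keeps a
26-participant cohort under ten seconds. Spectral synthesis runs at the
next 2-3-5-smooth FFT length and truncates, which is legitimate because
the process is stationary within each interval.

Fixed generator choices (made once, as plausible for a homogeneous
young-adult cohort, and not revisited): reference log band powers follow a
1/f profile with an alpha bump (broadband RMS ~ 10-15 µV); per-participant
broadband gain SD 0.3 (log), per-band offsets SD 0.1, per-segment jitter SD
0.05; latent R-states drawn from a normal with mean 6.5 and SD 1.5 clipped
to [1, 9] (relaxing scenes rate above the midpoint); reported labels are
the latent value plus Gaussian noise (`labelNoiseSd`, default 0.5),
rounded and clipped; SAM valence rises and arousal falls with relaxation.
Dropout flags `round(fraction * n)` segments — a deterministic count, so
the default 7/78 always leaves exactly 71 usable segments.

What the generator does **not** emulate: ocular and muscle artifacts,
electrode drift and impedance changes, genuine nonstationarity beyond the
relaxation envelope, volume conduction, or any physiological claim about
*which* bands respond to relaxation — the response slopes are free
parameters, and the defaults (mild alpha increase, beta decrease) are a
convention, not a finding. Passing tests therefore demonstrate that the
pipeline recovers a band-power signal when one exists and stays calibrated
when none does; they do not validate the physiology of relaxation.

## Preprocessing

The front end is a 1-45 Hz zero-phase Butterworth band-pass. The package
uses order 6 per pass: order 4, which one might default to, leaves about
3-4% of a 60 Hz mains tone after forward-backward application at 256 Hz,
while order 6 reaches the intended stop-band rejection (>= 40 dB, measured
0.6%) and is still numerically stable in transfer-function form.
Forward-backward application keeps the four analysis sections aligned
(zero phase).

Edge handling matters at the 1 Hz corner, whose transient decays over
seconds. Stand-alone filtering pads the signal by autoregressive extension
(an AR(16) fit to each end, extrapolated 2 s): tones continue exactly and
noise continues statistically, so there is no boundary kink for the filter
to ring on. The classical odd-reflection pad leaves 2-9% RMS of spurious
edge energy on a mid-swing tone (scipy's default behaves identically);
AR-extension brings that to ~0.6%. Pipeline-internal filtering instead
slices the recording with a 2-second real-data margin, uses the cheap
reflection pad, and trims the margin.

Bands are the canonical seven: delta 1-3, theta 4-7, low alpha 8-10, high
alpha 10-12, low beta 12-20, high beta 20-30, gamma 31-50 Hz. Gamma's
band-pass is realized as 31-45 Hz to honor the front-end cut; its
nominal definition is retained. The filterbank applies one order-4
zero-phase Butterworth per band. Shared edges (10, 12, 20 Hz) belong to
both adjacent pass bands, so a tone exactly on an edge splits roughly
50/50 between neighbors, and band energies are approximately — not exactly
— additive: broadband 1-45 Hz noise loses ~7% of its energy to the
inter-band gaps the canonical band table leaves (3-4, 7-8, 30-31 Hz) plus
~10% to order-4 skirt roll-off. Sharper (higher-order) narrow-band designs
are numerically singular in transfer-function form at 256 Hz, so order 4
stands.

Sections are cut with 0-based half-open sample markers: `pre` is the last
`sectionLengthS` (default 30 s) before viewing onset, `begin`/`end` the
first/last `sectionLengthS` of the viewing, `post` the first
`sectionLengthS` after it. A viewing shorter than twice the section length
makes `begin` and `end` overlap; this is allowed with a warning (the 90-s
scene with 60-s sections is the boundary case).

## The feature bank

The model dictionary has exactly 147 columns:
\(\{E, EE, DE, PSD\} \times 7\ \text{bands} \times 3\ \text{channels} = 84\)
plus \(ER \times \binom{7}{2}\ \text{pairs} \times 3 = 63\). The
enumeration is adopted because it reproduces the documented count exactly;
asymmetry features are therefore excluded from the model set and used only
in the statistics set, which appends ASM, DASM and RASM over the two alpha
bands and ERASM over all 21 pairs (174 columns). Definitions:

* `E`: \(\sum_i x_i^2\) (Parseval-equivalent to the summed squared
  spectrum over \(n\)).
* `ER(a, b)`: \(E_a / E_b\), lower band first in the canonical order.
* `EE`: Shannon entropy \(-\sum_i p_i \log p_i\) of sub-window energy
  fractions; the literal-form alternative \(\sum_i \log p_i^2\) is kept as
  a `literal` mode of [energyEntropy()].
* `DE`: \(\tfrac12\log(2\pi e \sigma^2)\) with the unbiased variance —
  the differential entropy of a Gaussian, standard for band-limited EEG.
* `PSD`: the Yule-Walker AR(8) spectrum
  \(\hat\sigma^2_p / (f_s\,|1 - \sum_k \hat a_k e^{-2\pi i f k / f_s}|^2)\)
  averaged over the band's slice of a 512-point \([0, f_s/2]\) grid
  (two-sided density; flat at \(1/f_s\) for unit white noise). A
  periodogram fallback with a warning covers ill-conditioned fits.
* Asymmetries, with the conventional sign orientations:
  `ASM = E(right) - E(left)`, `ERASM = ER(right) - ER(left)`,
  `DASM = DE(left) - DE(right)`, `RASM = DE(left)/DE(right)`.

**Granularity.** Section-level tables (the statistics stage) compute every
feature once per 30-s section: energy over the whole section, `EE` over
1-s sub-windows (so uniform energy gives \(\log 30\)), the AR spectrum on
the full section. Fragment-level tables (the model stage) follow the
per-second protocol: all 147 features on consecutive 1-s epochs, then the
sliding window's mean. This split is deliberate. One-second band energies
of a 2-3 Hz-wide band carry only ~4-6 degrees of freedom, so per-epoch
energy *ratios* are nearly heavy-tailed-infinite-variance quantities;
averaging 30 of them does not tame the tails, and paired t-tests on such
features over-reject (we measured a null rejection rate of ~0.07 instead
of 0.05). Computing section statistics at section scale restores nominal
calibration (measured 0.052 over 50 null cohorts). Within the 1-s model
epochs, `EE` uses 0.125-s sub-windows (8 per epoch), since a 1-s
sub-window would be degenerate there.

The per-epoch engine vectorizes the Yule-Walker fit (batched
Levinson-Durbin on per-epoch autocovariances) and matches `stats::ar.yw`
to machine precision, including its \(n/(n-p-1)\) innovation-variance
inflation; a test asserts the equality epoch by epoch.

## Group statistics

For each feature, the paired difference `section_b - section_a` is formed
per segment (the pairing unit is the viewing, not the participant) and
tested with a two-sided paired t-test. Zero-variance difference vectors
are reported with the degenerate convention `t = 0, p = 1,
direction = none`. The `begin_post` comparison is deliberately not
offered: early-viewing mood swings and post-viewing decay make it
uninterpretable. No multiple-testing correction is applied by default
(matching the field's common practice for this screen);
Benjamini-Hochberg is available and recommended when the full bank is
screened. Consistency is a separate, deliberately strict criterion:
per-participant segment-averaged deltas must all share one strict sign
(tolerance configurable; zero deltas count against).

## The regression stage

Fragments inherit their segment's label. The seven enhancement presets
pair a model window (the last 30 or 60 s of viewing) with 50%-overlapping
windows of 2, 4, 6 or 8 s; `N = (L - W)/step + 1` fragments per segment,
so 71 segments yield 2,059 rows under the densest preset.

Eight regressors are provided. Linear regression and RBF support-vector
regression (cost 1, epsilon 0.1) consume train-fold-standardized features;
tree ensembles consume raw features. Random forest uses 100 trees
(ranger). The boosting family uses 100 rounds at learning rate 0.1:
`GB` is depth-3 gradient boosting and `XGB` depth-6 regularized gradient
boosting (both via xgboost's exact grower), while `LGBM` is leaf-wise
histogram gradient boosting (31 leaves, xgboost's `lossguide` grower —
the LightGBM growth strategy). AdaBoost.R2 (linear loss, weighted-median
prediction, depth-3 trees) and bootstrap-aggregated trees are implemented
in-package over rpart. All stochastic fits draw per-fold sub-seeds from
one master seed and are bit-reproducible.

Evaluation is leave-one-subject-out: one fold per participant, all of a
participant's fragments held out together, MAE and
\(\mathrm{ACC} = 1 - \tfrac1n\sum |y_i - \hat y_i| / y_i\)
computed per fold and averaged. ACC can be negative for very poor
predictions and is not clipped. Metrics are computed per fragment by
default; segment-level aggregation (the exact mean of a segment's
fragment predictions) is available via `segmentPredictions()`.

**Stacking.** The first level is RFR, AdaBoost, GB and LGBM; the second a
simple LR or SVM. The classical single-loop protocol — pool the LOSO
out-of-fold base predictions to train the meta model, then score each
participant on the across-fold *average* of base predictions — is
available as `scheme = "single_loop"`, but note that 25 of the 26
averaged fold models have seen the scored participant, so this protocol
is optimistically biased. The default `scheme = "nested"` runs an inner
LOSO inside every outer training set, refits the bases on the outer
training set, and never lets the held-out participant influence any
fitted model; the per-fold training-row audit is exposed in the result
and asserted in the tests. The bias direction (literal >= nested in
accuracy) is itself verified by a paired simulation test. A deployable
stack (`fitStack()`/`predictNewCohort()`) refits the bases on all data and
freezes the feature dictionary; new cohorts must match it column for
column.

## Numerical and degenerate-input conventions

Natural logarithms throughout; unbiased (n-1) variance; 0-based half-open
sample markers; trailing partial seconds are truncated when epoching;
energy ratios with zero denominators, RASM with zero `DE(right)`, zero
total energy in `EE`, and zero variance in `DE`/`PSD` raise typed errors
rather than propagating NaN; the AR spectrum falls back to the
periodogram with a warning when the fit is ill-conditioned. Channel
reports follow the FP1/FPZ/FP2 canonical order; readers accept channels
case-insensitively in any order.

## Problem sizes used by the checks

The packaged checks run the full study geometry where it matters — 26
participants, 78 segments, 71 usable — for the type-I calibration (50
null cohorts), the injected-signal recovery (20 cohorts), the LGBM LOSO
benchmark and the stacking run (group 1: 2,059 fragments x 147 features).
Unit tests exercise the same code paths on 4-8 participant cohorts, which
keeps the default suite comfortably within an interactive development
loop.

## Known limitations

* The filterbank's band energies are not exactly additive (shared -3 dB
  edges, inter-band gaps of the canonical band table); treat cross-band
  energy comparisons as approximate.
* ACC divides by the true label, so it weights errors at low R-state
  heavily; comparisons across cohorts with different label distributions
  are not meaningful.
* The literal stacking scheme's scores should be read as
  protocol-faithful, not as unbiased generalization estimates.
* EDF support is a minimal 16-bit codec (one 1-s record per block,
  markers in a JSON sidecar), sufficient for interchange of this
  package's sessions, not a general EDF+ implementation.
* Synthetic validation bounds what can be claimed about real EEG; see
  the generator section.
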