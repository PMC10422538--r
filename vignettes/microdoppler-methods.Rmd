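---
title: "Methods: simulated functional ultrasound of drug-evoked CBV dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulated functional ultrasound of drug-evoked CBV dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(microdoppler)
```

## The problem this package addresses

Functional ultrasound (fUS) maps brain activity through cerebral blood
volume (CBV): ultrafast plane-wave imaging produces long bursts ("Doppler
ensembles") of complex IQ frames in which slow-moving red blood cells leave
a weak, phase-rotating echo buried under tissue clutter that is typically
three to four orders of magnitude stronger. In the pharmacological tremor
model this package targets, a rodent receives a tremorgen (harmaline) after
a 30-minute baseline; motor-cortex and thalamic CBV rises by on the order
of +160 % and then decays over hours, and a beta-blocker (propranolol)
given later transiently suppresses the response. The electrophysiological
correlate is tremor-band (≈5 Hz and ≈30 Hz) oscillation in the local field
potential (LFP).

No public dataset exists for this preparation, so the package pairs every
processing stage with a synthetic-data generator that produces IQ
ensembles, plane-wave channel data, and LFP traces with the statistical
structure the analysis assumes — and with the ground truth recorded, so
each stage can be tested as a parameter-recovery problem rather than by
visual inspection.

## Acquisition model

The acquisition defaults mirror a high-frequency small-animal protocol:
a 128-element linear array at 16 MHz transmit frequency, five plane-wave
angles equally spaced on ±14°, a pulse repetition frequency of 5 kHz
(so the compounded frame rate inside an ensemble is 1 kHz), 400-frame
ensembles every 2.5 s. `acquisition_config()` enforces the cross-field
invariant `prf = num_angles × frame_rate`.

Element pitch (100 µm) and imaging depth are documented defaults of this
package, not measured properties of any particular probe.

## The synthetic scene

`hemodynamic_scene()` freezes a ground-truth world from a single seed:

* **Vessel geometry.** A Bernoulli vessel mask (densities 0.35 inside the
  two rectangular ROIs, 0.06 elsewhere) on a 64 × 64 grid. The "active"
  ROI stands in for the motor cortex, the "control" ROI for a
  non-responding region; atlas-registered anatomy is out of scope.
* **Blood signal.** Each vessel pixel carries a single-scatterer Doppler
  tone `a √m(t) exp{i(2π f_d n/f_r + φ_0 + w_n)}` with
  `f_d = 2 v f_c / c`, per-pixel speed `v ~ U(1, 10) mm/s` (Doppler shifts
  ≈21–208 Hz, safely under the 500 Hz Nyquist limit; faster pixels are
  flagged as aliased, never clipped), amplitude jitter `U(0.7, 1.3)`, and
  a random-walk phase `w_n` with 0.2 rad/frame steps. The walk gives the
  tone a finite linewidth (decorrelation time ≈50 ms), which is what real
  blood speckle has; with nearly pure tones the blood subspace collapses
  onto a few strong singular directions and the filter's behaviour becomes
  unrepresentative (see *Threshold margin* below).
* **Tissue clutter.** An exactly rank-`r` (default 3) sum of outer
  products: frozen smooth complex spatial modes times slow temporal modes
  (sums of sinusoids below 2 Hz, drawn per ensemble from one band per mode
  — drift, respiration-like, faster wobble — with 1/r power weights).
  Total clutter power is 40 dB above the reference blood power. A low-rank
  construction, rather than simulated tissue motion, gives the SVD filter
  a provable target: the blood-free, noise-free Casorati matrix has
  numerical rank ≤ r, and any residual clutter after rejection is exactly
  measurable.
* **Noise.** I.i.d. circular complex Gaussian noise 10 dB below blood.
* **Determinism.** Scene-level draws are frozen at construction; each
  ensemble's draws come from a stream seed derived from
  `(scene seed, ensemble time)`, so any ensemble can be regenerated in
  isolation, bit-identically.

These default ratios are chosen so that the unfiltered power image is
clutter-dominated (the pipeline demonstrably fails without the filter) and
the filtered one recovers truth.

## Hemodynamic time course

The multiplier applied to active-ROI blood power is

    m(t) = 1                                          t < t0
    m(t) = 1 + A·c·(1 − e^{−Δ/τ_rise})·e^{−Δ/τ_decay}  Δ = t − t0 ≥ 0

with `c` fixed so the maximum equals `1 + A` (default `A = 1.6`, i.e.
+160 %). The defaults `τ_rise = 180 s` and `τ_decay = 7200 s` encode an
onset over minutes and a decay over hours, the qualitative course of
harmaline tremor; neither constant is a measured value. The propranolol
arm multiplies the *elevation* `m(t) − 1` by `1 − d·g(t − t_s)`, where `g`
rises over a short onset constant (60 s) and recovers with `rebound_tau`;
`d = 1` therefore suppresses fully back to baseline, and the short onset
ramp keeps the multiplier continuous (an instantaneous dip would not be).
Because the reported timing of the suppressor injection is ambiguous in
this preparation (20 min after the tremorgen by one account, 45 min into
the session by another), `t_suppressor` is an explicit free parameter.

**Time compression.** A real session spans ~3 h (≈4300 ensembles). The
generator exposes `time_compression` (default 60): ensembles are spaced
`2.5 s × 60 = 150 s` of session time apart, so 70 ensembles span the whole
protocol while every epoch boundary (30-min baseline, injections) keeps
its physiological position. All analysis windows are specified in session
time and scale together.

A consequence worth stating plainly: the 10-sample smoothing kernel used
for display traces spans 25 min of compressed session time instead of the
25 s it spans at the real cadence. A moving average is bounded by the
maximum of its input, so the smoothed trace peak recovers ≈150 % when the
instantaneous truth peaks at +160 %; the package's recovery tests
therefore check the smoothed peak against the band 145–175 % rather than
the instantaneous value. The raw (unsmoothed) trace peak recovers the
truth without this bias.

## SVD clutter filtering

Each ensemble is reshaped losslessly into its space × time Casorati matrix
(`to_casorati()`), decomposed by a complex economy SVD, and reconstructed
from the singular orders above a global threshold (`svd_filter()`).
Magnitude-only filtering is rejected outright — the Doppler information is
in the phase. The energy identity
`‖low‖² + ‖kept‖² + ‖residual‖² = ‖input‖²` holds to 10⁻⁶ relative and is
tested, as is agreement with an independent reconstruction from the
eigendecomposition of the Gram matrix on small matrices.

**Threshold selection.** The rejection order is chosen per ensemble by the
*energy knee* rule: the index of maximum discrete curvature of the
log-singular-value spectrum, i.e. where the decay flattens from the steep
clutter block into the blood/noise continuum. A degenerate (flat) spectrum
falls back to a fixed order (default `ceil(0.15 × ensemble_len)`) with a
warning. The session median of per-ensemble thresholds is logged, since a
single session-wide threshold is an equally defensible reading of a
"global" threshold.

**Threshold margin.** `low_cut_margin` (default 1) orders are rejected on
top of the knee. The tradeoff was measured on the default scene: each
extra rejected order removes a slice of blood signal — and preferentially
the *strongest post-injection* blood directions, which biases the active
ROI downward and the control ROI upward by a few percent per order —
while an under-cut by one order leaves a clutter mode ~30 dB above blood
in the image, which is catastrophic. One order of insurance against knee
under-detection (observed with short ensembles) is the default; margin 0
recovers the evoked amplitude essentially exactly when the clutter rank is
known.

**No high-order cut by default.** Noise handling belongs to the bias
stage, not the filter; the pipeline does ask `svd_filter()` for the
top-tail reconstruction (last 25 % of orders), but only to *estimate* the
noise, and adds it back into the image band.

## MicroDoppler formation and noise bias

"Coherent integration" of the filtered ensemble is implemented as the
per-pixel mean of squared magnitudes (power Doppler). Integrating the
complex samples before the modulus would cancel the Doppler phases and
destroy precisely the signal the filter isolated, so that reading is
rejected. The mean, not the sum, is used so images are comparable across
ensemble lengths.

Two noise-bias estimators are provided (`estimate_noise_profile()`):

* `vessel_free_region`: per-depth median power in a declared vessel-free
  mask, broadcast laterally — unbiased and simple when such a mask exists.
* `high_order_residual` (pipeline default): per-pixel mean power of the
  SVD top-tail residual, rescaled to the target band. The naive rescale by
  the dimension ratio is *wrong*: the SVD sorts directions by energy, so
  the bottom quarter of singular orders of a white-noise matrix carries
  only ≈15 % of the noise energy, not 25 %. The estimator divides by the
  Marchenko–Pastur energy fraction of the bottom tail (computed by
  quadrature of the MP density for the matrix's aspect ratio), which makes
  it unbiased to a fraction of a percent at the default geometry.

Subtraction clamps at zero (power is nonnegative); the clamp fraction and
the subtracted map are kept as diagnostics.

## Functional activation mapping

Activation is reported as percent change,
`100 × (P_t − baseline)/baseline`, relative to the pixel-wise mean over
the baseline window (default the full 30-min pre-injection epoch; at least
3 images required). The raw difference maps are retained alongside.
Pixels whose baseline power falls below the 1st percentile of the
*vessel-region* baseline are flagged invalid rather than allowed to divide
by near-zero; when no vessel mask is supplied the vessel region is crudely
segmented as pixels above 5 % of the image's 99.5th power percentile.
ROI traces average valid pixels only (the count is recorded per frame) and
are therefore invariant to whatever values invalid pixels carry.
Trace smoothing is a centred 10-sample moving average with *shrinking*
windows at the edges — no reflected or padded phantom values at the ends
of the session, where injection times are read off.

## Time-point statistics

The contrast compares the `±5`-frame windows of the *raw* ROI-mean trace
centred on two session times (window centres snap to the nearest frame,
ties to the earlier frame; a window that would be clipped by the session
boundary is an error, never silently shortened; the two windows must not
overlap). The samples are the 11 per-frame ROI means — the temporal
reading of the averaging window — with a pixels-at-one-frame mode
deliberately not provided, because consecutive-frame ROI means are
independent across ensembles in this design whereas pixels within one
frame are not exchangeable units.

The Wilcoxon–Mann–Whitney test itself is implemented in the package:
midranks for ties; exact two-sided p by the count-distribution recurrence
for `n1 + n2 ≤ 12` tie-free samples; otherwise the normal approximation
with tie-corrected variance and continuity correction. Tests verify the
exact path against brute-force enumeration of all labelings to 10⁻¹², the
approximation against the exact law, and the null calibration of the full
contrast path on no-drug pipeline runs. P-values are two-sided and
uncorrected for multiplicity, matching the analysis this package mirrors.

## Electrophysiology arm

`simulate_lfp()` produces tremor oscillators (defaults 5 and 30 Hz) whose
amplitudes follow `1 + g(m(t) − 1)` with the same time course as the
imaging arm (evaluated at compressed time), plus 60 Hz line contamination
and 1/f background noise. Preprocessing decimates to 2 kHz through a
DC-normalised anti-alias FIR, band-passes 0.1–500 Hz (zero-phase
Butterworth: order-2 high-pass, order-4 low-pass), and applies zero-phase
second-order notches (Q = 30) at 60 Hz and harmonics up to the band edge.

Spectrograms use the multitaper method with discrete prolate spheroidal
(Slepian) tapers computed in-package from the symmetric tridiagonal
formulation — Sturm-count bisection for the top eigenvalues plus
tridiagonal inverse iteration — which is exact, fast at window lengths of
20 000 samples, and verified against a dense eigensolve at small sizes.
Defaults: 10 s windows, 5 s step, time-bandwidth 3, 5 tapers, which
resolves 5 Hz with margin at 2 kHz and yields ±0.3 Hz concentration
half-bandwidth. Windows are demeaned before tapering. Normalisation
divides each frequency by its mean over the baseline epoch (a ratio, with
dB left as a display choice); band power is the per-window mean over bins
inside the band.

## Beamformer validation harness

The main pipeline consumes generator IQ directly; the delay-and-sum
beamformer exists to validate the acquisition geometry. Channel data for
point scatterers uses the standard plane-wave delay
`τ = (x sinθ + z cosθ)/c + √(z² + (x−x_e)²)/c` with a Gaussian-windowed
tone burst. Reconstruction converts traces to analytic signals before
summation (so the output is IQ-like), interpolates linearly in fast time,
and applies an f-number-limited (default 1.0) Hann receive apodization;
none of these details are prescribed by the protocol this mirrors, so all
are configurable. Tests check forward–inverse consistency (PSF peak within
one grid cell), linearity, and that 5-angle compounding never widens the
mainlobe; grid spacing in those tests is 50 µm ≈ λ/2.

## Problem sizes, tolerances, determinism

The reference scenario is a 64 × 64 grid, 70 ensembles of 400 frames
(Casorati matrices 4096 × 400), compression 60. Unit tests run reduced
replicas (16–32 px grids, 48–200 frame ensembles) of the same physics;
the recovery and null-calibration suites state their scales inline. All
randomness flows from explicit seeds (one config seed fans out to scene
and ephys stage seeds; per-ensemble streams derive from the scene seed and
ensemble time), so reruns are bit-identical and `run_pipeline()` manifests
record output digests.

Known limitations: no speckle statistics or full-wave acoustics, no
motion artifacts or registration, no aliasing correction (flagged only),
rectangular ROIs instead of atlas anatomy, and a session container in RDS
form rather than a hierarchical binary format. Passing tests demonstrate
correct recovery under the generator's assumptions — rank-limited clutter,
white noise, tone-like blood — not performance on any animal dataset.
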