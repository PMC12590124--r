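---
title: "Methods: evoked and induced oscillation analysis in visoscil"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evoked and induced oscillation analysis in visoscil}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`visoscil` analyzes single virtual-sensor epochs of visually driven
cortical activity: phase-locked evoked components and non-phase-locked
induced oscillations, their band-limited features, group statistics, and
classification. This vignette documents the model behind each stage, the
tunable parameters, the numerical choices, and what the synthetic cohort
generator does and does not emulate.

## The signal model

An epoch runs from −200 to 500 ms around stimulus onset, sampled at
1 kHz with both endpoints included (701 samples). The package models a
trial as the sum of three parts:

* **Evoked components** — Gaussian-envelope deflections
  `a · p · exp(−(t − μ)² / 2w²)` with amplitude `a` (arbitrary units,
  since source waveforms have no absolute physical scale here), polarity
  `p = ±1`, center latency `μ` inside a named component window
  (M100/N1: 40–100 ms, M150/P1: 100–150, M250/N2: 150–250,
  M500/P3: 250–500) and envelope SD `w` in ms. Latency jitters across
  trials with a small SD (default 5 ms) so the component stays
  phase-locked; the window widths make 5 ms negligible.
* **Induced bursts** — Gaussian-envelope sinusoids whose carrier phase
  is drawn uniformly on each trial, in beta (15–29 Hz), narrowband gamma
  (30–100 Hz) or broadband gamma (100–250 Hz). `duration` is the
  envelope FWHM in ms; the envelope SD is `duration / (2√(2 ln 2))`. A
  `phase_locked` switch fixes the phase at zero for fidelity
  experiments.
* **1/f background** — spectrally shaped Gaussian noise: white Fourier
  coefficients scaled by `f^(−exponent/2)` (default exponent 1) and
  inverted, rescaled to the requested SD.

Uniform-random phase is what dissociates the two response modes: the
expected trial average of a random-phase burst shrinks as `1/√n_trials`
while its per-trial power is unchanged, which is exactly the contrast the
evoked/induced decomposition measures.

Amplitude scales are arbitrary-unit choices, not literature values; the
defaults (`noise_scale = 1`, burst/component amplitudes order 1) were
fixed once when the generator was written. What the generator does *not*
emulate: multichannel sensor geometry and field spread, forward/inverse
modelling, ocular or cardiac artifacts, non-stationary background
spectra, or correlated noise between trials. Passing tests therefore
demonstrate correctness of the analysis chain under the stated
statistical structure, not robustness to every property of real
recordings.

## Preprocessing

Filtering uses a 4th-order IIR Butterworth band-pass (1–100 Hz or
100–250 Hz) plus 2nd-order band-stop notches of ±2 Hz at 60, 120, 180,
240 Hz, skipping harmonics outside the pass band. Application is
zero-phase (forward–backward, `signal::filtfilt`) by default so that
component-peak latencies carry no filter delay; a causal single-pass
mode exists for fidelity experiments. The DC offset is removed per
trial. Trials are filtered independently with odd-symmetric reflection
padding (up to 500 samples) to suppress edge transients; steady-state
assertions in the tests exclude the first and last 100 ms of continuous
records.

Epoching is inclusive of both endpoints — "−200 to 500 ms" fixes 701
samples at 1 kHz — and events whose window leaves the record are dropped
with a warning. The stimulus artifact at −10…+10 ms is replaced by the
straight line between the endpoint samples, per trial; a mask records
the interpolated samples, and all later statistics start at +10 ms so
the interpolated segment never enters an analysis window.

Outlier-run exclusion estimates each feature's spread from the reference
condition's trial-level values and drops a run when any feature deviates
by *strictly more than* 3 SD (a run at exactly 3.0 SD is kept).
Zero-spread features are skipped with a warning rather than treated as
infinite z-scores, which degenerate synthetic inputs would otherwise
trigger.

## Component detection

Envelopes are natural cubic splines through the interior local extrema
(maxima for the upper, minima for the lower envelope) plus the
endpoints; a monotone waveform has no interior extrema and falls back to
the endpoint line, flagged. Spline interpolation rings near unequal
endpoint knots, so envelope accuracy assertions apply away from the
epoch edges.

Detection operates per component window on the envelope matching the
expected polarity (the raw average is available via `on = "waveform"`).
The threshold is the mean prestimulus magnitude plus 3 prestimulus SDs
— the prestimulus statistic itself was an open choice and is documented
as mean |x| + 3·SD(x) over −200…0 ms, interpolated samples excluded.
The boundary is inclusive: a peak at exactly threshold counts as
detected. Ties resolve to the larger magnitude, then the earlier
latency. Windows are half-open on the left (except the first) so a
latency belongs to exactly one component; EEG-like peaks (N1/P1/N2/P3)
use the same latency ranges with alternating expected polarity starting
negative. Detection is identical for sensor- and source-level waveforms;
provenance is metadata only.

## Time–frequency engine

Complex Morlet wavelets with 5 cycles: envelope SD
`σ_t = n_cycles / (2π f)` seconds, evaluated over ±3σ_t and unit-energy
normalized so raw power is comparable across frequencies before
flattening. Transforms are computed by FFT convolution on
reflection-padded epochs; samples closer than half the wavelet support
(3σ_t) to an epoch edge are flagged invalid, and band features and
statistics never consume invalid pixels. At very low frequencies the
support exceeds the epoch and the whole row is invalid — the cost of
analyzing 1 Hz wavelets on 700 ms epochs, flagged rather than hidden.
Frequency grids run in 1 Hz steps: 1–100 Hz (evoked), and 1–30 / 30–100 /
100–250 Hz separately for induced maps. 100 Hz occurs in two grids and
is assigned to narrowband gamma during feature extraction.

**Power and amplitude.** Power is the squared magnitude of the wavelet
coefficient; amplitude, where the oscillation criterion needs it, is its
square root.

**Spectral flattening** multiplies each bin by its frequency to undo 1/f
decay, for ranges within 1–100 Hz only — the correction overcompensates
above 100 Hz, so the 100–250 Hz range stays unadjusted. Flattening is
applied before baseline correction; for the relative-power-change ratio
the factor cancels, so the order only matters for raw-power outputs and
the oscillation mask. A useful side effect: flattening removes the
small downward argmax bias that unit-energy wavelets have on the
frequency axis.

**Baseline correction** maps power to relative power change,
`RPC = 100 · (P − B_f) / B_f`, with `B_f` the mean baseline
(−200…0 ms) power at frequency `f`, using edge-valid baseline samples
when at least 10 exist at that frequency and the whole baseline window
otherwise.

**Evoked vs induced.** Induced maps decompose every trial, flatten and
baseline-correct per trial, and average the corrected maps; averaging
corrected maps (rather than correcting an averaged power map) matches
the per-trial definition of induced activity and makes the map invariant
to trial order. Evoked maps decompose the trial average (computed as the
average of per-trial coefficients — the transform is linear). The evoked
background `B_f`, however, is the **mean per-trial baseline power**, not
the baseline power of the average. This was the one genuinely open design
point, and the per-trial background was chosen for two reasons: (i) it
puts evoked and induced maps on a common background scale, so activity
that cancels in the average yields near-zero evoked RPC instead of being
re-inflated by an equally cancelled baseline — without this, the
evoked/induced dissociation that defines the two modes disappears; and
(ii) the baseline of an averaged waveform has only a handful of effective
degrees of freedom per frequency, so ratios against it make the RPC peak
location hostage to baseline noise, while pooling all trials stabilizes
it.

**Oscillation criterion.** A pixel is a genuine oscillation when its
amplitude is at least (inclusive) twice the background amplitude at that
frequency, the background being the mean baseline-period amplitude —
baseline-period activity was chosen over a broadband noise-floor
estimate as the more conservative and simpler reading. Baseline-corrected
maps retain their uncorrected power so the criterion stays computable.

## Band features and normalization

Within a band × window rectangle (beta/NBG/BBG × 10–500 ms by default;
narrower presets such as 10–190 ms can be configured), the feature set is
the maximum-RPC pixel's frequency, latency and value, plus the mean RPC
over the rectangle. Ties resolve to the earliest latency, then the
lowest frequency. Peak search is not gated on the oscillation mask by
default; gating is available but off, since the mask is a reporting
criterion rather than part of the feature definition. Beta features use
15–29 Hz even though the induced low-range grid spans 1–30 Hz.

Min–max normalization `(x − min) / (max − min)` across participants
addresses inter-individual scale differences; all-equal inputs are an
error (zero denominator), and callers skip such features. For
descriptive statistics normalization spans all participants; inside the
classifier the default refits the scaling on each training split
(leakage-safe), with a global mode available for fidelity.

## Group statistics

Rank-sum tests use the exact distribution when the combined sample size
is ≤ 12 without ties, and the tie- and continuity-corrected normal
approximation otherwise. FDR control is Benjamini–Hochberg step-up,
applied within each analysis family (across windows; across the features
of a band). Spearman correlations are exact for n ≤ 9 without ties,
t-approximated otherwise. The regression stage is ordinary least squares
with intercept, categorical subtype as a binary indicator, and an
explicit rank-deficiency error naming aliased columns.

The cluster-based permutation test uses pixelwise pooled-variance
two-sample t statistics on the 10–500 ms window, thresholded at the
two-sided critical value for pixel α = 0.05. Suprathreshold pixels form
clusters under 4-neighbor adjacency by default ("neighboring pixels"
admits either convention; 8-neighbor is a switch), positive and negative
clusters separately, with mass the sum of t. The null is the maximum
absolute cluster mass over whole-subject label permutations (default
1,000), sampled uniformly with a seed; a cluster is significant when its
absolute mass exceeds the 99th percentile of the null (cluster formation
threshold and significance percentile are independent knobs, matching
the two stated criteria; a conventional cluster-α = 0.05 preset is the
95th percentile), and its Monte Carlo p is `(1 + #{null ≥ mass})/(n_perm
+ 1)`, so the smallest attainable p is `1/(n_perm + 1)`. Absolute mass
is used for the percentile (two-sided reading). Pixels invalid in any
subject's map are excluded before clustering.

## Classification

Features surviving one-way ANOVA with BH-FDR (q = 0.05) — after removing
features flagged as medication-associated — feed an RBF-kernel SVM with
C = 10. The kernel bandwidth is not specified by the design, so the
median heuristic (γ = 1/(2·median pairwise squared distance) on the
training data) is used and recorded per run, with a fixed-γ override.
Two evaluation regimes are reported side by side, since their
relationship is ambiguous in the design: stratified 10-fold
cross-validation, and 1,000 stratified 80/20 train–test splits whose
per-split metrics provide the mean ± SD distributions and the AUC pool.
Splits whose test set lacks a class are re-drawn and counted.
Confusion metrics leave zero-denominator ratios missing rather than
zero. ROC curves sweep the unique scores; the trapezoidal AUC equals the
rank-statistic (concordance) estimator, Youden's index picks the
operating point. Bootstrap AUC comparison resamples each pool 10,000
times and reports the two-sided empirical p
`min(1, 2·min(P(Δ ≤ 0), P(Δ ≥ 0)))` — the sidedness had to be fixed here
and two-sided is the conservative choice. The modality likelihood-ratio
test compares nested maximum-likelihood logistic models by
Δdeviance ~ χ²(df = added features); separation-induced non-convergence
is flagged and handled by a lightly ridge-penalized fit whose deviance is
reported with the flag.

## Numerical and testing notes

* All randomness is seeded; generator subject seeds derive
  deterministically from the cohort seed, and seeded functions restore
  the caller's RNG state.
* The cohort container is a directory of per-subject CSV matrices
  (written as `%.17g`, so float64 round-trips are bit-exact) with a JSON
  metadata sidecar.
* Connected-component labelling of suprathreshold pixels is compiled
  (Rcpp) because the permutation null evaluates it thousands of times.
* Test problem sizes were chosen to exercise each property at desk
  scale: 85-trial subjects for the evoked/induced dissociation and
  single-subject recovery checks; 200 replicate null cohorts of 15 + 15
  subject maps at 200 permutations for the cluster test's type-I error
  (the nominal any-significant-cluster rate at the 99th percentile is
  0.01); 50 replicates for cluster localization of a planted 50 %
  suppression; 20 replicate cohorts of 20 + 20 subjects for amplitude-
  ratio recovery; 500 replicates for the LRT null calibration. Null and
  planted-effect cohorts for the cluster test are simulated directly at
  the subject-map level, since the test's level depends only on
  exchangeability of subject labels, not on how the maps arose.
* The peak-amplitude feature is a power-scale (RPC) quantity, so a
  generated waveform-amplitude ratio ρ appears as ≈ ρ² in the feature
  ratio; parameter-recovery checks take the square root to report the
  recovered amplitude ratio.

## Known limitations

Common-average referencing has no analogue for a single virtual sensor
and is out of scope, as are multichannel envelope logic, forward/inverse
modelling, and artifact projection. Wavelet rows below ~13 Hz on 700 ms
epochs are mostly edge-flagged; beta-band conclusions rest on the upper
part of the band, and 1–10 Hz content in the low-range induced maps is
baseline-corrected against the full baseline window out of necessity.
The cluster test assumes exchangeable subjects (no within-subject
designs), and the classifier implements no hyperparameter search beyond
the fixed C.
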