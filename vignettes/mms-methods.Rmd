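---
title: "Micro-movement spikes: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Micro-movement spikes: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmspike)
```

This vignette is the package's account of its own methods: the
standardization that turns raw physiological series into micro-movement
spikes (MMS), the Gamma process model fitted to the spike amplitudes, the
heart-rate-variability and information-dynamic descriptors built on top,
what the synthetic-data generator does and does not emulate, and the
numerical conventions adopted where the underlying procedure leaves a
choice open.

## 1. The MMS standardization

Facial landmark tracking at 30 Hz gives per-landmark pixel trajectories;
differentiating the (optionally spline-smoothed) positions by central
differences and taking the Euclidean norm gives a speed magnitude series in
pixels/s. ECG gives R-peak times, whose successive differences are the
inter-beat intervals (IBI) in ms. Both are positive scalar series, and both
run through the identical transform (`mms_transform()`, `ibi_mms()`):

1. detect the raw series' local peaks (slope sign change + to −; the
   flanking valleys are sign changes − to +);
2. fit the Gamma family to the raw peak magnitudes by maximum likelihood
   and take the fitted mean m = âb̂ (which equals the sample mean of the
   peaks exactly — a property of the Gamma MLE this package also exploits
   in its generator);
3. form the deviation series d = |x − m| (a `positive_only` flag restricts
   to positive deviations instead);
4. at each local peak of d, emit the spike
   `Peak / (Peak + Avg)`, where `Avg` is the mean of the **original**
   series over the closed valley-to-valley interval around the peak; all
   other frames are exactly zero.

Two properties are load-bearing and asserted in the test suite. First,
frame preservation: the spike train has the same length as the input, so
two streams recorded on the same clock stay aligned. Second, exact scale
invariance: multiplying the input by any k > 0 multiplies m, every
deviation peak and every local average by k, leaving each spike unchanged.
This is the allometric normalization that makes spike amplitudes
comparable across faces of different sizes and hearts of different base
rates.

The denominator convention deserves a note. Averaging the *deviation*
series over the closed interval instead would bound every spike below by
1/2 (a closed-interval mean can never exceed its maximum), collapsing the
spike distribution's lower half and making small-amplitude regimes
unrepresentable. Averaging the original-scale signal — the local mean
speed, or the local mean IBI — gives spikes the full (0, 1) range, with
small average speeds producing larger normalized fluctuations, which is
the behaviour the normalization is meant to capture. The closed interval
includes both endpoint valleys; plateaus count once, at their first index;
a boundary sample is a valley when the series moves upward away from it.
These tie-break rules make peak detection deterministic and equal to a
brute-force sign scan, which the tests verify on random series.

## 2. The Gamma process model

Spike amplitudes (only the non-zero peaks; the structural zeros are not
data) are modelled as draws from the two-parameter Gamma family in
shape–scale form. `fit_gamma_mle()` solves the profile score
log(a) − ψ(a) = log(x̄) − mean(log x) by Newton iteration and sets
b̂ = x̄/â. Confidence intervals use the observed information at the MLE,
inverted in closed form so that near-degenerate samples (shape in the
millions from almost-constant peaks) remain numerically stable; an exactly
constant sample is returned as a flagged degenerate fit rather than an
error. The asymptotic-information choice for the intervals is this
package's own; a cross-check against `fitdistrplus::fitdist` and a
log-likelihood grid search is part of the test suite, and CI coverage is
verified at about 95% over 400 simulated fits.

The derived descriptors are closed forms and are asserted as identities
for every fit: mean ab, variance ab², NSR (variance/mean) = b, skewness
2/√a. The NSR is the noise axis of the analysis: a higher scale means a
more dispersed, noisier spike process, and, through the cohort-level
log₁₀(scale) ~ log₁₀(shape) law (`fit_loglog_law()`, ordinary least
squares), a lower shape closer to the memoryless exponential. Per-region
NSR triplets (V1/V2/V3) are summarized by their Euclidean norm from the
origin, paired with the matching skewness norm (`nsr_skew_summary()`), and
condition contrasts are plain pain-minus-control differences
(`delta_params()`).

The 68-point landmark grid is partitioned into the trigeminal regions as a
*data object* (`face_regions()`): the published index listings are
internally inconsistent (V1 described as 26 points but listing 27; V2
described as 17 but listing 16 under an ascending reading of its ranges,
one of which is written descending), so membership is supplied as a table
with the documented counts 27/16/25 rather than silently forced totals,
and every pooling function accepts a replacement table.

## 3. Heart-rate variability descriptors

`poincare_sd()` summarizes the lag-1 IBI scatter by the SDs along the two
45° ellipse axes: SD1² = Var(x₍t+1₎ − x₍t₎)/2 (beat-to-beat,
parasympathetic) and SD2² = Var(x₍t+1₎ + x₍t₎)/2 (longer-term,
sympathetic), with population (1/n) variance throughout — the magnitudes
depend on that convention, so it is fixed and documented. This rotated-axes
form makes the equivalence with an explicit ellipse-axis projection exact
(tested at 1e-6); the classical SD2 = √(2 Var(x) − SD1²) expression agrees
up to O(1/n) edge terms and is asserted approximately.

`band_powers()` resamples the tachogram to a uniform 4 Hz grid by cubic
interpolation and estimates the spectrum by Welch's method — 60-s Hann
windows at 50% overlap, one-sided scaling chosen so the PSD integrates to
the signal variance (checked against a Parseval-style identity within 5%).
Power is integrated over the conventional LF (0.04–0.15 Hz, sympathetic)
and HF (0.15–0.40 Hz, parasympathetic) bands. The Welch implementation is
in-package because no installed package provides one; the segment length,
overlap and window are exposed through the function's arguments. Records
shorter than one cycle of the lowest LF frequency are rejected.

`detect_r_peaks()` removes baseline wander with a running median (~0.6 s),
band-passes 5–25 Hz with a zero-phase (forward–backward) Butterworth
filter, picks local maxima above an adaptive threshold with a 250 ms
refractory period, and refines each candidate to the local maximum of a
Gaussian-smoothed detrended copy, which keeps a symmetric R deflection's
peak at its exact sample. Intervals outside 300–2000 ms are flagged as
artifacts: retained in the raw series, excluded from Poincaré and fitting.

## 4. Transfer entropy

`transfer_entropy()` estimates T(source→target) =
H(Y_t | Y past) − H(Y_t | Y past, X past) with history length L over
non-overlapping complete windows, aggregating by the mean; the defaults
mirror the study's windowing (50-frame windows, 10% history so L = 5,
300-frame span at 30 Hz). Two estimators are provided:

* **binned** — equal-frequency discretization (4 bins by default, computed
  over the full span so bins are consistent across windows; a `binarize`
  option reduces to spike/no-spike) and plug-in joint entropies. It is
  transparent and has the known small-sample bias ≈ df/(2N ln 2) under
  independence, which the tests verify against the analytic value; a
  shuffled source collapses into the same band. For a deterministic lagged
  copy, TE saturates at the discretized-alphabet entropy.
* **gaussian** — restricted vs full linear autoregressions per window,
  TE = ½log₂(RSS_restricted/RSS_full): non-negative by construction and
  equal to the analytic Gaussian TE for linear coupling (tested to 1e-3).

With L = 5 histories the binned estimator's 4⁵-state conditioning
saturates inside a 45-sample window, so both directions collapse toward
zero; directional analyses at the standard windowing therefore use the
gaussian estimator, and direction recovery on coupled synthetic cohorts
(strength 0.8, lag 5) succeeds in ≥95% of seeds. The binned estimator
remains the default for low-order configurations where its transparency
and analytic bias are an advantage. The signed entropy definition
H = −Σ p log₂ p is used throughout; conditional-mutual-information and
entropy-difference forms of TE are algebraically identical and the
implementation computes the latter. Heart spike trains are aligned to the
30 Hz face grid by placing each beat's spike at the frame containing its
R-time (`mms_to_frames()`). Cohort-level curves sort participants by one
direction's TE (ties broken by participant id) and carry the opposite
direction along (`build_te_curves()`).

## 5. Cohort statistics

Rank-based comparisons deliberately avoid distributional assumptions the
Gamma fits themselves violate for normal-theory tests: pairwise two-sided
Wilcoxon rank-sum matrices (raw p-values by default, Benjamini–Hochberg
behind a flag), tie-corrected Kruskal–Wallis with Tukey–Kramer-type
pairwise intervals on mean joint ranks (a pair is significant when its
interval excludes zero, the disjoint-interval rule), and the Friedman test
for complete participant × condition blocks (an all-tied block design is
reported as statistic 0, p = 1 rather than NaN).

Distribution-level comparisons use the exact 1-D Wasserstein-1 distance
between empirical spike samples (`emd_1d()`, the integral of |F₁ − F₂|;
equal-size samples reduce to the mean absolute difference of sorted
values). The operands are the raw spike samples, not fitted densities on a
grid — fitting first would launder estimation error into the distance; a
practitioner wanting density-based distances can pass fitted-density draws
instead. The distance matrix feeds average-linkage hierarchical clustering
cut at k = 8 by default, with per-cluster condition compositions.
`delta_linear_fit()` regresses facial on cardiac NSR shifts and reports
R², adjusted R² and RMSE = √(SSE/(n−2)), the degrees-of-freedom
convention of standard curve-fitting summaries.

## 6. The synthetic cohort generator

The generator exists so that every stage has a recoverable truth. Its
central device is an *exact algebraic inversion* of the MMS transform
(`gen_ibi_series()`, `gen_face_landmarks()`): target spike values are
drawn first, and a series is constructed whose standardization reproduces
them exactly, not approximately. The construction interleaves
near-baseline samples (the only raw local maxima, centred so their mean —
and hence the fitted Gamma mean, by the MLE property — is exactly the
baseline) with three-sample excursions dipping below it; with the
excursion shoulders at half the dip depth, the spike equation inverts in
closed form, D = s·c/(1 − 0.6 s). For landmark tables the same profile is
realized as the *central-difference speed* of an integrated path with a
fixed random heading per landmark, by solving the two-term recursion
v_t = 2w_t − v₍t−1₎; shoulder/depth ratio 1/2 makes the alternating sums
telescope so speeds stay near the baseline, and the tail after the last
spike descends strictly below baseline so the boundary frames add no
spurious peaks. The tests confirm spike-exact round trips (1e-9) through
`speed_profile()` + `mms_transform()` across seeds and durations.

The inversion is exact on a representable window, s ∈ [0.004, 0.55] at the
defaults; draws outside are redrawn. The window is a structural limit: a
spike near 1 would require the local average to vanish, i.e. the signal to
hover near zero over a widening interval. At physiological noise levels
(mean spike ≈ 0.1–0.2) the excluded mass is of order 1e-4 and recovery
studies sit at nominal CI coverage; regimes whose Gamma mass extends above
~0.55 are truncated, and indeed any regime with appreciable mass above 1
is impossible for a quantity bounded in [0, 1), so high-mean high-scale
specifications can only ever be realized approximately.

`gen_coupled_cohort()` emulates the study design: 21 participants (the
cohort with simultaneous face and heart recordings), four tasks, control
and pain conditions, 30 Hz streams of 120 s by default. Per-record Gamma
signatures are drawn on the log–log law (slope −1, intercept −1, residual
SD 0.05 — values representative of published biorhythm parameter planes);
pain shifts the NSR upward by draws of mean 0.10, SD 0.05 (matching the
order of the published control-to-pain delta scatters), with pain shapes
placed back on the law. Facial and cardiac shifts are linked linearly with
noise calibrated to a target R² (default 0.84); the calibration subtracts
the *analytic* Gamma-estimation variance of the downstream fits from the
noise budget, so the target describes the fitted relation, not the latent
one — at too-short stream lengths the target becomes unattainable and the
generator warns and uses zero shift noise. Directed coupling mixes the
target stream's spike amplitude with the source's lagged amplitude,
target_t = (1−strength)·own_t + strength·source₍t−lag₎, a linear form with
an analytic Gaussian-TE limit; note that strong amplitude mixing distorts
the target's marginal distribution, so NSR-shift analyses are run with
coupling off. ECG waveforms place a unit Gaussian R deflection (40 ms
FWHM) at each R-time with additive white noise (SD 0.05 by default), at
which the detector's sensitivity exceeds 99% within one sample.

All randomness flows from explicit seeds through an isolated RNG scope
(`withr::with_seed`), so identical configurations are byte-identical and
the caller's RNG state is never touched.

What the generator does *not* emulate: landmark estimation error and
dropped video frames (trajectories are jitter-free, so smoothing is off by
default in `region_mms_samples()`), ECG morphology beyond the R deflection
(no P/T waves), respiration coupling, non-stationarity within a recording,
and any dependence structure between spikes beyond the injected lagged
coupling. Passing tests on synthetic cohorts therefore demonstrate that
the estimators recover what they claim from data satisfying the model's
assumptions — not that real recordings satisfy them.

## 7. Problem sizes and numerical conventions

The shipped studies use sizes chosen to make sampling error small relative
to the tolerances they assert: 400 fits at n = 1000 for CI coverage;
600-s IBI records (~187 spikes) and 30-s landmark tables (~6000 pooled V1
spikes) for regime recovery; 40 seeds at 300 frames for TE direction
recovery; 100 seeds of 40-point cohorts for power-law recovery; 20
participants at 60 s for the end-to-end shift detection. Thresholds on
coverage-style statements leave binomial room (e.g. ≥85% at 30 seeds for a
nominal 95% property) rather than sitting on the knife edge.

Other conventions, fixed and exposed: spline smoothing uses a fixed
degrees-of-freedom fraction (0.05 of the series length, floor 4) chosen to
attenuate white noise more than tenfold while passing linear trends
unchanged; derivatives are central differences (one-sided at the ends) for
oracle simplicity; Gamma fitting requires 30 values by default
(configurable floor); degenerate flat segments in the spike normalization
are skipped and counted, not fatal; a report bundle lists every artifact
with its SHA-256 checksum and the configuration echo, and reruns under a
fixed seed are byte-identical.

## 8. Known limitations

The Gamma CIs are asymptotic; at a few dozen spikes they are approximate
(a bootstrap option would be the next step). The binned TE estimator is
unusable at deep histories (state explosion) and the gaussian estimator
captures only linear coupling; nearest-neighbour estimators are future
work. The EMD clustering inherits hierarchical clustering's sensitivity to
linkage choice (exposed as an argument). The generator's representable
spike window truncates extreme regimes, and its calibration of the
delta-NSR relation is first-order (asymptotic variances); both are
documented above. Post-pain conditions are accepted in input vocabularies
but excluded from the default control-vs-pain comparisons.
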