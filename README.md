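# mmspike

Micro-movement spike (MMS) analysis of facial and cardiac biorhythms in R.

Pressure pain changes how the body moves at scales invisible to the naked
eye: facial landmarks jitter by fractions of a pixel, and the heart's
inter-beat intervals (IBI) fluctuate beat to beat. `mmspike` implements a
standardized analysis of those micro-fluctuations for researchers comparing
physiological states (e.g. a pain condition against a pain-free control)
across motor tasks. Both signal families — per-landmark facial speed
profiles from 30 Hz video tracking, and IBI sequences from ECG R-peaks —
are reduced to the same unit-free data type, so facial and cardiac noise
can be compared, regressed on each other, and probed for directed coupling.

## The model

Every positive scalar series (speed magnitude in pixels/s, or IBI in ms) is
standardized into **micro-movement spikes**. With m the empirically
estimated Gamma mean of the raw series peaks, each local peak of the
absolute deviation series |x − m| becomes a spike

    MMS = Peak / (Peak + Avg)

where `Avg` is the mean of the original series over the closed
valley-to-valley interval bracketing that peak. Spikes live in [0, 1),
zeros mark frames at the mean motion level, and the local averaging scales
out allometric (anatomical size) effects: multiplying the series by any
k > 0 leaves every spike unchanged.

The spike amplitudes are then fitted by maximum likelihood with the
continuous Gamma family in the shape–scale parameterization
f(x; a, b) = x^(a−1) e^(−x/b) / (b^a Γ(a)). Its derived descriptors drive
all downstream comparisons:

* **NSR** (noise-to-signal ratio) = variance/mean = the scale b;
* **skewness** = 2/√a — shape a = 1 is the memoryless exponential, large a
  approaches Gaussian symmetry;
* across a cohort, log₁₀(b) falls on a line in log₁₀(a) with negative
  slope (the shape–scale power law), so one parameter predicts the other.

Around that core the package provides: Poincaré SD1/SD2 and Welch LF/HF
band powers (0.04–0.15 / 0.15–0.40 Hz) for heart-rate variability; windowed
transfer entropy in bits between face and heart spike streams (50-frame
windows, 10% history, 300-frame span by default, binned plug-in and
linear-Gaussian estimators); Wilcoxon/Kruskal–Wallis/Friedman rank
comparisons of NSR across tasks and conditions; exact 1-D earth mover's
distance between empirical spike distributions with average-linkage tree
clustering; and ordinary least squares of facial on cardiac control→pain
NSR shifts. A synthetic-cohort generator inverts the MMS transform exactly,
so every stage can be validated against known ground truth.

## Worked example

```r
library(mmspike)

# a 5-minute synthetic heart recording whose spike amplitudes are exact
# Gamma(shape = 2, scale = 0.05) draws
ibi <- gen_ibi_series(base_ibi = 800, regime_spec(shape = 2, scale = 0.05),
                      duration = 300, seed = 42)
fit <- fit_gamma_mle(ibi_mms(ibi)$peak_values)
fit
#> <gamma_fit> shape 2.16 [1.581, 2.739], scale (NSR) 0.0448 [0.03128, 0.05832], n = 93
gamma_moments(fit)
#> # A tibble: 1 × 4
#>     mean variance    nsr skewness
#> 1 0.0968  0.00434 0.0448     1.36
```

Both injected parameters sit inside their 95% intervals; the NSR equals
the fitted scale, and skewness 1.36 = 2/√2.16. The same record yields the
standard HRV descriptors:

```r
poincare_sd(ibi)
#> <poincare_summary> SD1 = 36.20 ms, SD2 = 54.63 ms (372 pairs)
band_powers(ibi)
#> <spectral_bands> LF 384 ms^2, HF 1.18e+03 ms^2, LF/HF 0.325
```

At the cohort level, a 21-participant synthetic study (control and pain
conditions, resting task) recovers the injected shape–scale law, the
linear face–heart noise-shift relation, and the control-vs-pain rank-sum
separation:

```r
cc  <- gen_coupled_cohort(cohort_config(n_participants = 21,
                                        tasks = "resting", seed = 1))
res <- run_cohort_analysis(cc$cohort)
res$powerlaw$heart
#> <powerlaw_fit> log10(scale) = -1.009 -1.004 log10(shape), R^2 = 0.996, n = 42
res$delta_fits
#> # A tibble: 1 × 7
#>   task    r.squared adj.r.squared   rmse slope intercept  nobs
#> 1 resting     0.905         0.900 0.0157 0.992   0.00199    21
res$ranksum
#> # A tibble: 2 × 3
#>   task    stream     p_value
#> 1 resting face   0.000000111
#> 2 resting heart  0.000000192
```

The generator placed the cohort on a slope −1 law (recovered −1.004,
R² 0.996), tied facial to cardiac NSR shifts with target R² 0.84
(fitted 0.905 on this seed), and shifted every pain record's NSR upward
(rank-sum p ≈ 1e-7 for both streams). `autoplot()` methods display spike
trains, fitted densities, the log–log parameter plane, Poincaré scatters
and sorted/matched transfer-entropy curves.

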