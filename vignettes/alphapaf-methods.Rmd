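---
title: "Estimating peak alpha frequency: model, algorithm, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating peak alpha frequency: model, algorithm, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alphapaf)
```

## The problem

The peak alpha frequency (PAF) — the frequency at which the alpha rhythm
(here 7–13 Hz) of a resting power spectrum attains maximum power — is a
widely used electrophysiological trait marker. It increases through
childhood, differs between clinical groups, and correlates with cognitive
measures. Estimating it well is harder than reading off the spectral
maximum, because neural power spectra are dominated by an aperiodic $1/f$
trend: raw maxima are biased toward the low-frequency edge of the alpha
band, and spectra without any genuine alpha peak still have a maximum
somewhere. `alphapaf` implements a detrend-then-parameterize estimator with
an explicit validity rule, plus everything needed around it to run a
group-level analysis: Welch spectral estimation, atlas aggregation, a
statistics layer, and a synthetic-cohort generator.

## The estimation model

A resting power spectrum for one cortical parcel is modelled as

$$
P(f) \;=\; \underbrace{10^{\,c - b \log_{10} f}}_{\text{aperiodic}}
\;\times\;
\Big(1 + a\, e^{-(f-\mu)^2 / 2\sigma^2}\Big),
$$

with aperiodic offset $c$ (log\(_{10}\)-power at 1 Hz), exponent $b \ge 0$,
and a single alpha peak of relative height $a$, center $\mu$ (the PAF) and
width $\sigma$. The estimator inverts this model in five steps
(`estimate_paf()`):

1. **Log–log transform** of power and frequency over the fit range
   (default 1–55 Hz), where the aperiodic component is a straight line.
2. **Robust line fit** (`fit_aperiodic()`): iteratively reweighted least
   squares under the Huber loss with tuning constant 1.35 on
   MAD-standardized residuals. The Huber loss grows linearly beyond the
   threshold, so the narrow alpha bump — a coherent positive outlier — is
   down-weighted and the broadband trend is recovered; ordinary least
   squares would be dragged upward across the alpha band.
3. **Detrending** (`detrend_spectrum()`): the fitted line is subtracted
   from the log spectrum.
4. **Exponentiation and band isolation** (`isolate_alpha()`): residuals are
   mapped back through $10^x$, so a peakless spectrum sits at 1, and
   restricted to 7–13 Hz (endpoints inclusive on the discrete grid).
5. **Gaussian fit** (`fit_gaussian_peak()`): bounded least squares of
   $a\,e^{-(f-\mu)^2/2\sigma^2} + 1$. The vertex $\mu$ is the PAF.

A fit is **valid** only if it converges with $a > 0$ and
$7 \le \mu \le 13$. The center is deliberately allowed to travel outside
the band during optimization ($\mu \in [5, 15]$): a spectrum whose best
vertex lies at, say, 6.5 Hz has no distinct alpha peak and must be
excludable, which requires the optimizer to be able to say so. Invalid fits
carry a reject reason (`outside_band`, `no_convergence`,
`non_positive_amplitude`, `empty_residual`) and are excluded from regional
averages, with the exclusion bookkeeping exposed by `validity_summary()`.

## Spectral estimation

`segment_recording()` cuts a recording into consecutive non-overlapping
5-s segments, drops the trailing remainder, and rejects subjects with
fewer than 10 complete segments (a 50-s floor) via a typed condition that
the pipeline converts into a logged exclusion. `welch_psd()` averages
one-sided periodograms of Hamming-tapered, mean-removed windows. Two
conventions were genuinely open:

* **Window placement.** An "80% overlap of 5-s epochs" can mean sub-windows
  inside each epoch or 5-s windows slid across the record. Only a 5-s
  window produces the 0.2 Hz bin spacing the analysis assumes
  ($\Delta f = 1/T = 1/5\,\mathrm{s}$), so the default slides 5-s windows
  with 80% overlap across the concatenated accepted segments. Because the
  segments are consecutive pieces of one continuous recording, windows are
  allowed to straddle segment junctions;
  `respect_segment_boundaries = TRUE` switches to one periodogram per
  segment instead.
* **Scaling.** Density scaling (power per Hz) is used. Everything consumed
  downstream — the log–log slope, the exponentiated residual, relative
  alpha power — is invariant to the scaling convention.

`relative_alpha_power()` is the band-to-total power ratio
(7–13 Hz over 1–55 Hz, endpoints inclusive).

## Atlas aggregation

The 68 cortical Desikan-Killiany parcels are grouped into ten lobar
regions: {left, right} × {cingulate, frontal, occipital, parietal,
temporal}. The insula belongs to none of the five lobes; the shipped
mapping (`dk_region_mapping()`, `inst/extdata/dk10_mapping.tsv`) marks its
two parcels `unassigned` rather than inventing an assignment, so regional
aggregation covers 66 parcels while parcel-level validity bookkeeping still
counts all 68. A user mapping that absorbs the insula into a lobe is fully
supported (`load_mapping()`). Regional PAF is the unweighted mean over the
region's valid parcels — missing when a region has none — and regional
relative alpha power is the unweighted mean over all its parcels.

## The statistics layer

* `two_sample_t()`: pooled-variance Student t (Welch behind a flag),
  oriented as second group minus first, so ASD-then-TD reports TD − ASD.
* `chi_square_2x2()` / `chi_square_rxc()`: Pearson tests; the Yates
  continuity correction is an explicit per-call flag with no silent
  default, because the two published contrasts this reproduces imply
  different choices.
* `fit_ols_robust()`: OLS point estimates with heteroscedasticity-consistent
  sandwich standard errors. HC1 is the default flavor (the convention of
  the major commercial statistics packages); HC0/HC3 are selectable. The
  model F is a robust Wald test of the non-intercept terms.
* `region_interaction_scan()`: per-region models
  `paf ~ diagnosis + moderator + diagnosis:moderator` (diagnosis coded
  ASD = 1, TD = 0), with Benjamini–Hochberg step-up control at $q = 0.05$
  across the ten focal-term p-values. The family is per analysis (the ten
  interaction p-values of one moderator scan), not the pool of all scans:
  each analysis is one table and one decision problem. Missing regional
  PAFs are handled listwise per region.
* `per_group_regression()`, `subscale_scan()`: follow-up simple
  regressions within a group, and the deliberately uncorrected
  per-subscale exploration of one region at $\alpha = 0.05$.
* `fit_lmm_region_diagnosis()`: `outcome ~ region * diagnosis +
  (1 | subject)` by REML, Wald z statistics, reference region left
  cingulate. When the random-intercept variance collapses to zero the
  model falls back to OLS with cluster-robust (by subject) standard
  errors, which is the same fixed-effect estimator in that limit.

## The synthetic-cohort generator

`simulate_cohort()` emulates a two-group child cohort: 19 ASD and 24 TD
subjects; ages uniform over 60–89 / 60–91 months (only the ranges are
published, so uniform is the least-informative choice); SRS total t-scores
67.6 ± 14.3 vs 46.4 ± 6.4; K-ABC MPS 103.1 ± 16.7 vs 115.4 ± 12.4 and ACH
98.0 ± 17.8 vs 107.4 ± 13.7; male fractions 13/19 and 14/24. Each subject
carries 68 parcel spectra whose true peak centers are

$$
\mu_{sp} = \text{baseline}_{r(p)} +
\beta_{r(p), g(s)} \,(\text{age}_s - \overline{\text{age}}_{g(s)}) +
u_s + v_{sp},
$$

with a diagnosis-specific age slope $\beta$ (default: 0.053 Hz/month in
both cingulate regions for the ASD group only, zero elsewhere), a shared
subject effect $u_s \sim N(0, 0.45^2)$ and parcel jitter
$v_{sp} \sim N(0, 0.3^2)$. A per-group fraction of parcels (5% ASD, 2% TD,
matching the published validity rates) has no alpha peak at all. The noise
scales are not published; they were derived once from the published
regression standard errors — a follow-up slope SE of 0.014 with $n = 19$
and age SD 7.5 months implies a regional residual SD near 0.46 Hz — and
fixed. With roughly four to eleven parcels per region, subject-level
variation dominates the regional mean, so
$\sqrt{0.45^2 + 0.3^2/\bar{n}_p} \approx 0.46$ Hz reproduces that residual
scale. A consequence worth stating: at this effect and noise scale the
interaction t-statistic is about 2.9, so single-cohort BH-corrected
detection power is moderate (roughly one half to two thirds), not near 1 —
the tests therefore assert unbiased recovery and confidence-interval
coverage over many cohorts, not near-certain per-cohort detection.

**Spectrum model.** `simulate_spectrum()` draws
$P(f) = 10^{\,c - b\log_{10} f + \varepsilon(f)} (1 + a e^{-(f-\mu)^2/2\sigma^2})$
with i.i.d. per-bin log-power noise $\varepsilon \sim N(0, s^2)$. Two
points of this design are deliberate. Noise enters on log power, keeping
simulated power strictly positive and matching the log-domain fitting.
And the peak is *multiplicative* — a Gaussian bump of the detrended,
exponentiated residual — because that is the exact generative inverse of
the estimator: with an additive linear-power peak over a steep $1/f^2$
background, the vertex of the exponentiated residual shifts upward by
about $b\sigma^2/\mu$ ($\approx$ 0.2 Hz at $b = 2$), and "recovering the
configured center" would be ill-defined. Under the multiplicative model,
noiseless recovery is exact to optimizer precision.

**Time series.** `simulate_timeseries()` shapes white noise in the Fourier
domain so the expected one-sided PSD equals the configured spectral model;
the alpha rhythm appears as a band-limited stochastic oscillation, not a
deterministic sinusoid. Spectral shaping was chosen over autoregressive or
filtered-noise constructions for exact expected-PSD control.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: volume conduction and source leakage between
parcels (parcel values are independent given the subject effect), multiple
or split alpha peaks, knee-shaped aperiodic components, non-stationarity
and artifacts within a recording, correlated bin noise from window
overlap, and any dependence of trait scores on PAF (metadata and spectra
are conditionally independent given group and age).

## Numerical choices

* Huber IRLS: scale re-estimated each iteration by MAD (consistency
  factor 0.6745), convergence at $10^{-8}$ relative coefficient change,
  at most 200 iterations. A perfectly linear log–log spectrum drives the
  robust scale to zero and defeats a relative convergence test; residuals
  at rounding error are accepted as converged.
* All logarithms base 10. Slopes and the PAF are base-invariant; the
  intercept convention (log\(_{10}\)-power at $\log_{10} f = 0$) is only a
  reporting choice.
* Gaussian fit: baseline fixed at 1 (the null level of an exponentiated
  log residual, and the level the residual floor actually hugs);
  `baseline = "free"` fits an additive offset instead. Initialization at
  the band argmax with $\sigma_0 = 1$ Hz; bounds $a \ge 0$,
  $0.1 \le \sigma \le 6$, $\mu \in [5, 15]$, validity tested on $[7, 13]$
  afterwards. On clean peaks the PAF is insensitive to the baseline
  convention; borderline validity calls may differ, which is why the
  convention is a documented flag rather than a hidden constant.
* Zero or negative power bins inside the fit range are floored at
  $10^{-6}$ times the smallest positive bin before the log transform, so
  degenerate synthetic inputs cannot crash the transform while real
  spectra are unaffected.
* Band endpoints are inclusive on the discrete grid, with an absolute
  tolerance of $10^{-8}$ Hz absorbing floating-point grid noise (7.0 and
  13.0 bins count).

## Problem sizes in the test suite

The suite exercises every stage at the full design size where it matters
(43 subjects × 68 parcels end to end in the acceptance script) and scales
Monte Carlo suites to what a laptop runs in seconds to a couple of
minutes: 200 seeded spectra for noisy PAF recovery, 2,000 fixed-seed
replicates for the robust-SE size check, 100 simulated cohorts for
interaction-coefficient coverage, 20–50 replicates for spectral
calibration checks. All Monte Carlo tests use fixed seeds and are
deterministic.

## Known limitations

Single-peak parameterization only (no theta/beta peaks, no multi-peak
decomposition, no aperiodic knee); the estimator inherits the usual
caveat that a strong non-alpha bump inside 7–13 Hz would be read as an
alpha peak. The pipeline starts at parcel-level time series or spectra:
sensor-space processing, source reconstruction and artifact rejection are
upstream of this package. Statistical tools implement the fixed analysis
design they document (two groups, ten regions, moderator-by-diagnosis
models); they are not a general modelling framework.
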