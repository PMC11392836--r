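# alphapaf

Estimation of the resting-state **peak alpha frequency (PAF)** from
region-level MEG/EEG signals, with the full group-level analysis around it.

The PAF — the frequency at which the 7–13 Hz alpha rhythm of a resting
power spectrum attains maximum power — is a developmental and clinical
biomarker. Reading it off the raw spectral maximum is unreliable: neural
spectra are dominated by an aperiodic 1/f trend that biases maxima toward
the low edge of the band, and spectra with no genuine alpha peak still
have a maximum somewhere. `alphapaf` implements the detrend-then-fit
estimator with an explicit validity rule. A parcel spectrum is modelled as

```
P(f) = 10^(c − b·log10 f) · (1 + a·exp(−(f − μ)² / 2σ²))
```

and estimated by: log–log transform over 1–55 Hz → robust line fit
(Huber's method, tuning constant 1.35) for the aperiodic component
`c − b·log10 f` → subtraction and exponentiation of the residual →
isolation of 7–13 Hz → bounded Gaussian least squares. The fitted vertex
`μ` is the PAF; fits whose vertex lands outside 7–13 Hz, fail to
converge, or carry non-positive amplitude are flagged invalid (no
distinct alpha peak) and excluded from aggregation.

Around the estimator:

* **Spectral stage** — 5-s segmentation with a 10-segment minimum, Welch
  PSD with Hamming tapers and 80% overlap (0.2 Hz bins at 500 Hz),
  relative alpha power.
* **Atlas stage** — 68 Desikan-Killiany parcels aggregated into ten lobar
  regions ({left, right} × {cingulate, frontal, occipital, parietal,
  temporal}), with valid/invalid bookkeeping.
* **Statistics stage** — pooled t-tests, chi-square contrasts, per-region
  `PAF ~ diagnosis × moderator` regressions with heteroscedasticity-robust
  (HC1) standard errors and Benjamini–Hochberg FDR control, within-group
  follow-ups, SRS-subscale exploration, and mixed-effects
  region-by-diagnosis models with a subject random intercept.
* **Synthetic cohorts** — a seeded generator of two-group cohorts (19 ASD
  + 24 TD children by default) with known aperiodic, periodic and
  group-level parameters, so the entire pipeline is testable end to end
  without raw recordings.

## Worked example

Estimate the PAF of one simulated spectrum:

```r
library(alphapaf)

cfg  <- spectrum_sim_config(aperiodic_exponent = 1.2, peak_amplitude = 0.6,
                            peak_center = 9.4, peak_width = 1.1, noise_sd = 0.05)
spec <- simulate_spectrum(cfg, seed = 42)
fit  <- estimate_paf(spec)
fit
#> <alpha_peak_fit> PAF=9.644 Hz (amplitude=0.485, width=1.026 Hz)
fit$aperiodic
#> <aperiodic_fit> intercept=0.0535 slope=-1.2346 (Huber k=1.35, converged)
```

The estimated PAF (9.64 Hz) sits within the per-bin noise of the
configured 9.4 Hz center, and the recovered aperiodic slope (−1.23)
matches the configured exponent 1.2.

Scan a simulated cohort for a diagnosis-by-age interaction — the
generator places an ASD-only age slope of 0.053 Hz/month in the two
cingulate regions:

```r
co   <- simulate_cohort(cohort_sim_config(seed = 8), spectra = FALSE)
pt   <- co$parcel_truth
pt$paf_hz <- pt$true_paf; pt$valid <- pt$has_peak
reg  <- aggregate_regions(pt)
scan <- region_interaction_scan(reg, co$metadata, moderator = "age_months")
scan$scan[, c("region", "coeff", "robust_se", "t", "p", "fdr_reject")]
#>             region     coeff robust_se       t       p fdr_reject
#> 1   left_cingulate  0.043215    0.0150  2.8848 0.00635      FALSE
#> 2  right_cingulate  0.045945    0.0176  2.6135 0.01267      FALSE
#> 3     left_frontal -0.009899    0.0167 -0.5926 0.55684      FALSE
#> ...
```

The interaction coefficients concentrate in the cingulate rows at about
the configured 0.053 Hz/month (sampling noise at n = 43 is ±0.018 per
cohort); at this realistic effect-to-noise ratio a single cohort often
misses the BH-corrected threshold, which is itself an instructive output
of the simulation. For a fully end-to-end run (spectra → PAF → regions →
statistics, with a manifest and rendered report):

```r
run_pipeline(pipeline_config(seed = 1), "run1")
write_report("run1")
```

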