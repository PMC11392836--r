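test_that("aperiodic fit recovers exact power laws and flat spectra", {
  s <- clean_spectrum(exponent = 2, amplitude = 0)
  fit <- fit_aperiodic(s)
  expect_equal(fit$slope, -2, tolerance = 1e-6)
  expect_equal(fit$intercept, 0, tolerance = 1e-6)
  expect_true(fit$converged)

  flat <- power_spectrum(default_grid(), rep(1, 271))
  fit0 <- fit_aperiodic(flat)
  expect_equal(fit0$slope, 0, tolerance = 1e-8)
  expect_equal(fit0$intercept, 0, tolerance = 1e-8)
})

test_that("the Huber fit resists the alpha bump better than OLS", {
  s <- clean_spectrum(exponent = 2, amplitude = 2, center = 10, width = 1)
  huber <- fit_aperiodic(s)
  keep <- s$freqs >= 1 - 1e-9 & s$freqs <= 55 + 1e-9
  ols <- lm(log10(s$power[keep]) ~ log10(s$freqs[keep]))
  expect_lt(abs(huber$slope - (-2)), abs(coef(ols)[2] - (-2)))
})

test_that("detrending is the exact subtraction identity", {
  s <- clean_spectrum(exponent = 1.5, amplitude = 0)
  fit <- fit_aperiodic(s)
  res <- detrend_spectrum(s, fit)
  expect_lt(max(abs(res$residual)), 1e-8)

  # line + log-domain bump: residual equals the bump exactly
  f <- default_grid()
  bump <- 0.3 * exp(-(f - 10)^2 / 2)
  s2 <- power_spectrum(f, 10^(1 - 2 * log10(f) + bump))
  fit2 <- structure(list(intercept = 1, slope = -2, tuning_constant = 1.35,
                         n_iterations = 0L, converged = TRUE),
                    class = "aperiodic_fit")
  res2 <- detrend_spectrum(s2, fit2)
  expect_equal(res2$residual, bump, tolerance = 1e-10)

  # exponentiated residual restricted to the band is the inverse-log identity
  band <- isolate_alpha(res2)
  expect_equal(band$freq_hz, seq(7, 13, by = 0.2), tolerance = 1e-9)
  expect_equal(band$value, 10^bump[f >= 7 - 1e-9 & f <= 13 + 1e-9],
               tolerance = 1e-10)
})

test_that("detrending residuals of noisy power laws are unbiased", {
  means <- vapply(1:100, function(s) {
    spec <- simulate_spectrum(
      spectrum_sim_config(aperiodic_exponent = 1.5, peak_amplitude = 0,
                          noise_sd = 0.05), seed = s)
    mean(detrend_spectrum(spec, fit_aperiodic(spec))$residual)
  }, numeric(1))
  expect_lt(abs(mean(means)), 0.005)
})

test_that("gaussian peak fitting recovers exact peaks and applies the validity rule", {
  f <- seq(7, 13, by = 0.2)
  y <- 0.5 * exp(-(f - 10)^2 / 2) + 1
  fit <- fit_gaussian_peak(data.frame(freq_hz = f, value = y))
  expect_true(fit$valid)
  expect_equal(fit$center, 10, tolerance = 1e-6)
  expect_equal(fit$amplitude, 0.5, tolerance = 1e-6)
  expect_equal(fit$width, 1, tolerance = 1e-6)

  # vertex below the band: excluded as having no distinct alpha peak
  y2 <- 0.5 * exp(-(f - 6.5)^2 / 2) + 1
  fit2 <- fit_gaussian_peak(data.frame(freq_hz = f, value = y2))
  expect_false(fit2$valid)
  expect_identical(fit2$reject_reason, "outside_band")
  expect_lt(fit2$center, 7)

  # no peak at all
  fit3 <- fit_gaussian_peak(data.frame(freq_hz = f, value = rep(1, length(f))))
  expect_false(fit3$valid)
  expect_true(fit3$reject_reason %in% c("non_positive_amplitude", "no_convergence"))
})

test_that("end-to-end PAF estimation recovers noiseless synthetic peaks", {
  for (center in c(10, 9)) {
    fit <- estimate_paf(clean_spectrum(exponent = 2, amplitude = 0.5,
                                       center = center, width = 1))
    expect_true(fit$valid)
    expect_lt(abs(fit$center - center), 0.1)
  }
  # pure 1/f: no distinct peak
  fit0 <- estimate_paf(clean_spectrum(exponent = 2, amplitude = 0))
  expect_false(fit0$valid)
})

test_that("PAF is invariant to overall spectral scale", {
  s <- clean_spectrum(exponent = 1.2, amplitude = 0.6, center = 9.5)
  f1 <- estimate_paf(s)
  s2 <- power_spectrum(s$freqs, s$power * 37.5)
  f2 <- estimate_paf(s2)
  expect_equal(f1$center, f2$center, tolerance = 1e-8)
  expect_equal(f2$aperiodic$intercept - f1$aperiodic$intercept, log10(37.5),
               tolerance = 1e-6)
})

test_that("every valid PAF lies inside the alpha band", {
  for (s in 1:40) {
    set.seed(s)
    cfg <- spectrum_sim_config(
      aperiodic_exponent = runif(1, 0.5, 2.5),
      peak_amplitude = runif(1, 0, 1),
      peak_center = runif(1, 5, 15),
      peak_width = runif(1, 0.5, 2), noise_sd = 0.1)
    fit <- estimate_paf(simulate_spectrum(cfg, seed = s))
    if (fit$valid) {
      expect_gte(fit$center, 7)
      expect_lte(fit$center, 13)
    }
  }
})

test_that("the bounded least-squares fit agrees with a dense grid search", {
  for (center in c(8.3, 10.7)) {
    s <- clean_spectrum(exponent = 1.5, amplitude = 0.4, center = center,
                        width = 1.3)
    fit <- estimate_paf(s)
    res <- detrend_spectrum(s, fit$aperiodic)
    band <- isolate_alpha(res)
    oracle <- gaussian_gridsearch(band$freq_hz, band$value)
    expect_lt(abs(fit$center - oracle["mu"]), 0.05)
  }
})

test_that("estimate_paf_table processes long tables and flags invalid parcels", {
  tab <- toy_spectra_table(c("S1", "S2"), c("lh_cuneus", "rh_cuneus"),
                           list(c(9, 10), c(10.5, 6.5)))
  fits <- estimate_paf_table(tab)
  expect_equal(nrow(fits), 4L)
  expect_equal(fits$valid, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(fits$paf_hz[1:3], c(9, 10, 10.5), tolerance = 1e-3)
  expect_identical(fits$reject_reason[4], "outside_band")
  expect_true(all(is.finite(fits$rel_alpha)))
})

test_that("degenerate paf inputs error or invalidate cleanly", {
  expect_error(band_config(alpha_band = c(0.5, 13)), class = "alphapaf_config_error")
  expect_error(fit_aperiodic(power_spectrum(c(1, 2), c(1, 1))),
               class = "alphapaf_config_error")
  # spectrum with zero bins inside the band
  res <- data.frame(freq_hz = c(1, 2, 3), residual = c(0, 0, 0))
  expect_error(isolate_alpha(res), class = "alphapaf_empty_residual")
  expect_error(fit_gaussian_peak(data.frame(freq_hz = c(7, 8, 9),
                                            value = c(1, 2, 1))),
               class = "alphapaf_config_error")
})
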