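test_that("pooled t-tests reproduce summary-based worked examples", {
  expect_equal(two_sample_t(n1 = 10, mean1 = 5, sd1 = 1,
                            n2 = 12, mean2 = 5, sd2 = 2)$t, 0)
  srs <- two_sample_t(n1 = 19, mean1 = 67.6, sd1 = 14.3,
                      n2 = 24, mean2 = 46.4, sd2 = 6.4)
  expect_lt(abs(abs(srs$t) - 6.493), 0.05)
  expect_equal(srs$df, 41)
  # vector interface agrees with stats::t.test
  set.seed(1)
  x <- rnorm(15); y <- rnorm(18, 0.5)
  mine <- two_sample_t(x = x, y = y)
  ref <- t.test(y, x, var.equal = TRUE)
  expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
  # zero pooled variance with unequal means flags an infinite statistic
  degen <- two_sample_t(n1 = 5, mean1 = 1, sd1 = 0, n2 = 5, mean2 = 2, sd2 = 0)
  expect_true(is.infinite(degen$t))
})

test_that("2x2 chi-square matches the cross-product formula and handles Yates", {
  for (tab in list(c(13, 6, 14, 10), c(20, 5, 8, 17), c(3, 9, 11, 2))) {
    a <- tab[1]; b <- tab[2]; c <- tab[3]; d <- tab[4]
    n <- sum(tab)
    formula_chi2 <- n * (a * d - b * c)^2 /
      ((a + b) * (c + d) * (a + c) * (b + d))
    got <- suppressWarnings(chi_square_2x2(a, b, c, d, correct = FALSE))
    expect_equal(got$statistic, formula_chi2, tolerance = 1e-10)
    expect_equal(got$df, 1)
  }
  expect_equal(suppressWarnings(
    chi_square_2x2(10, 10, 10, 10, correct = FALSE))$statistic, 0)
  expect_error(chi_square_2x2(0, 0, 5, 5), class = "alphapaf_config_error")
  # continuity correction reproduces the validity-rate contrast
  v <- chi_square_2x2(1227, 65, 1599, 33, correct = TRUE)
  expect_gt(v$statistic, chi_square_2x2(1227, 65, 1599, 33)$statistic - 2)
  expect_lt(v$p, 0.001)
})

test_that("r x c chi-square equals the direct independence formula", {
  tab <- matrix(c(95, 5, 97, 3, 90, 10, 96, 4, 92, 8,
                  85, 15, 93, 7, 94, 6, 91, 9, 88, 12), nrow = 10, byrow = TRUE)
  got <- chi_square_rxc(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(got$statistic, sum((tab - expected)^2 / expected),
               tolerance = 1e-10)
  expect_equal(got$df, 9)
  # identical row proportions -> 0
  same <- matrix(rep(c(30, 10), 4), nrow = 4, byrow = TRUE)
  expect_equal(chi_square_rxc(same)$statistic, 0)
  # 2x2 input consistent with the dedicated function
  expect_equal(chi_square_rxc(matrix(c(13, 6, 14, 10), 2, byrow = TRUE))$statistic,
               suppressWarnings(chi_square_2x2(13, 6, 14, 10))$statistic,
               tolerance = 1e-12)
})

test_that("robust OLS: exact noiseless fit, correct dfs, affine-invariant t", {
  x <- 1:20
  fit <- suppressWarnings(  # noiseless fixture: "essentially perfect fit"
    fit_ols_robust(y ~ x, data.frame(x = x, y = 2 + 3 * x)))
  expect_equal(fit$terms$coeff, c(2, 3), tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)

  md <- toy_metadata()
  reg <- toy_region_table(md, b_int = 0.05, sd = 0.4, seed = 2)
  sub <- merge(reg[reg$region == "left_cingulate", ], md)
  sub$diagnosis <- ifelse(sub$group == "ASD", 1, 0)
  m1 <- fit_ols_robust(paf_hz ~ diagnosis * age_months, sub)
  expect_equal(unique(m1$terms$df), 39)          # 43 subjects, 4 terms
  expect_equal(nrow(m1$terms), 4L)
  # homoscedastic and robust SEs share point estimates
  expect_equal(m1$terms$coeff,
               unname(coef(lm(paf_hz ~ diagnosis * age_months, sub))),
               tolerance = 1e-12)
  # standardizing a predictor leaves its t unchanged
  sub$age_z <- scale(sub$age_months)[, 1]
  m2 <- fit_ols_robust(paf_hz ~ diagnosis * age_z, sub)
  expect_equal(m1$terms$t[4], m2$terms$t[4], tolerance = 1e-8)
  # rank deficiency errors with the aliased term named
  sub$age2 <- sub$age_months * 2
  expect_error(fit_ols_robust(paf_hz ~ age_months + age2, sub),
               regexp = "age2", class = "alphapaf_config_error")
})

test_that("robust-SE inference holds its size under a heteroscedastic null", {
  rejections <- vapply(1:800, function(s) {
    set.seed(s)
    x <- runif(50)
    y <- 1 + rnorm(50, sd = 0.3 + 2 * x)   # variance grows with x, beta_x = 0
    fit <- fit_ols_robust(y ~ x, data.frame(x = x, y = y))
    fit$terms$p[fit$terms$term == "x"] < 0.05
  }, logical(1))
  expect_lt(abs(mean(rejections) - 0.05), 0.025)
})

test_that("BH decisions equal the brute-force step-up rule", {
  fam <- c(0.001, 0.008, 0.039, 0.041, 0.30, 0.60, 0.74, 0.90, 0.95, 1.0)
  got <- bh_fdr(fam, q = 0.05)
  expect_equal(got$reject, bh_bruteforce(fam, 0.05))
  expect_true(bh_fdr(0.04, q = 0.05)$reject)
  expect_false(any(bh_fdr(rep(1, 8), q = 0.05)$reject))
  for (s in 1:50) {
    set.seed(s)
    p <- runif(sample(3:20, 1))^sample(1:3, 1)
    expect_equal(bh_fdr(p, q = 0.05)$reject, bh_bruteforce(p, 0.05))
  }
  empty <- bh_fdr(numeric(0))
  expect_length(empty$reject, 0L)
})

test_that("the per-region scan recovers a deterministic generative model", {
  md <- toy_metadata()
  reg <- toy_region_table(md, b0 = 8, b_dx = -1.5, b_age = 0.02,
                          b_int = 0.053, sd = 0)
  scan <- suppressWarnings(  # noiseless fixture: "essentially perfect fit"
    region_interaction_scan(reg, md, moderator = "age_months"))
  expect_equal(nrow(scan$scan), 10L)
  expect_equal(scan$scan$coeff, rep(0.053, 10), tolerance = 1e-8)
  full <- scan$results[["left_cingulate"]]$terms
  expect_equal(full$coeff[full$term == "diagnosis"], -1.5, tolerance = 1e-7)
  expect_equal(full$coeff[full$term == "age_months"], 0.02, tolerance = 1e-9)
})

test_that("the scan concentrates interaction signal in the configured regions", {
  hits <- matrix(FALSE, nrow = 25, ncol = 10,
                 dimnames = list(NULL, region_labels()))
  ests <- numeric(25)
  for (s in 1:25) {
    co <- simulate_cohort(cohort_sim_config(seed = 1000 + s), spectra = FALSE)
    pt <- co$parcel_truth
    pt$paf_hz <- pt$true_paf; pt$valid <- pt$has_peak
    reg <- aggregate_regions(pt)
    scan <- region_interaction_scan(reg, co$metadata, moderator = "age_months")
    hits[s, scan$scan$region] <- scan$scan$p < 0.05
    ests[s] <- scan$scan$coeff[scan$scan$region == "left_cingulate"]
  }
  rates <- colMeans(hits)
  cing <- c("left_cingulate", "right_cingulate")
  expect_gt(min(rates[cing]), max(rates[setdiff(region_labels(), cing)]))
  # interaction estimate unbiased around the configured 0.053 Hz/month
  expect_lt(abs(mean(ests) - 0.053), 0.015)
})

test_that("per-group follow-up regressions use within-group dfs", {
  md <- toy_metadata()
  reg <- toy_region_table(md, b_int = 0.053, sd = 0.45, seed = 5)
  asd <- per_group_regression(reg, md, "left_cingulate", "ASD")
  td <- per_group_regression(reg, md, "left_cingulate", "TD")
  expect_equal(unique(asd$terms$df), 17)   # n = 19
  expect_equal(unique(td$terms$df), 22)    # n = 24
  md2 <- md; md2$age_months <- 70
  expect_error(per_group_regression(reg, md2, "left_cingulate", "ASD"),
               class = "alphapaf_config_error")
})

test_that("permuted group labels keep the follow-up rejection rate at its level", {
  md <- toy_metadata()
  reg <- toy_region_table(md, b0 = 9, sd = 0.45, seed = 8)
  rej <- vapply(1:400, function(s) {
    set.seed(s)
    md_p <- md
    md_p$age_months <- sample(md_p$age_months)   # break any association
    fit <- per_group_regression(reg, md_p, "left_cingulate", "TD")
    fit$terms$p[fit$terms$term == "age_months"] < 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.03)
})

test_that("subscale exploration returns one uncorrected model per subscale", {
  md <- toy_metadata()
  reg <- toy_region_table(md, sd = 0.4, seed = 9)
  out <- subscale_scan(reg, md)
  expect_equal(nrow(out), 5L)
  expect_false(any(is.na(out$p)))
  # affine invariance: a linear transform of a subscale gives identical t
  md$srs_awareness <- 2 * md$srs_cognition + 5
  out2 <- subscale_scan(reg, md, subscales = c("srs_awareness", "srs_cognition"))
  expect_equal(out2$t[1], out2$t[2], tolerance = 1e-8)
  md$srs_mannerism <- 50
  expect_error(subscale_scan(reg, md, subscales = "srs_mannerism"),
               class = "alphapaf_config_error")
  expect_error(subscale_scan(reg, md, subscales = "srs_missing"),
               class = "alphapaf_config_error")
})

test_that("the mixed model matches OLS in the zero-variance limit and counts dummies", {
  md <- toy_metadata(n_asd = 5, n_td = 5)
  # no subject-level variance: fixed region offsets only
  reg <- toy_region_table(md, b0 = 9, sd = 0)
  offsets <- seq(-0.4, 0.5, by = 0.1)
  reg$paf_hz <- reg$paf_hz + offsets[match(reg$region, region_labels())]
  long <- merge(reg, md[, c("subject_id", "group")])
  lmm <- suppressWarnings(fit_lmm_region_diagnosis(long))
  expect_equal(nrow(lmm$terms), 20L)   # 1 + 9 + 1 + 9 dummy columns
  long$diagnosis <- ifelse(long$group == "ASD", 1, 0)
  long$region <- relevel(factor(long$region), ref = "left_cingulate")
  ols <- lm(paf_hz ~ region * diagnosis, long)
  expect_equal(lmm$terms$coeff, unname(coef(ols)), tolerance = 1e-6)
})

test_that("the mixed model recovers known region offsets with subject noise", {
  md <- toy_metadata(n_asd = 5, n_td = 5, seed = 3)
  covered <- 0L
  n_rep <- 20L
  true_offset <- 0.6
  for (s in 1:n_rep) {
    reg <- toy_region_table(md, b0 = 9, sd = 0)
    reg$paf_hz[reg$region == "right_occipital"] <-
      reg$paf_hz[reg$region == "right_occipital"] + true_offset
    set.seed(s)
    subj_eff <- rnorm(10, 0, 0.3)
    reg$paf_hz <- reg$paf_hz + subj_eff[match(reg$subject_id, md$subject_id)] +
      rnorm(nrow(reg), 0, 0.1)
    long <- merge(reg, md[, c("subject_id", "group")])
    lmm <- suppressWarnings(fit_lmm_region_diagnosis(long))
    tr <- lmm$terms[lmm$terms$term == "regionright_occipital", ]
    covered <- covered + (abs(tr$coeff - true_offset) <= 2 * tr$se)
  }
  expect_gte(covered / n_rep, 0.9)
})

test_that("cohort descriptives assemble group contrasts from metadata", {
  co <- simulate_cohort(cohort_sim_config(seed = 21), spectra = FALSE)
  d <- cohort_descriptives(co$metadata)
  expect_equal(nrow(d$continuous), 4L)
  expect_equal(unname(d$n), c(19L, 24L))
  expect_equal(d$sex$df, 1)
  srs_row <- d$continuous[d$continuous$variable == "srs_total", ]
  expect_lt(srs_row$t, 0)  # TD - ASD orientation: ASD scores higher
})
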