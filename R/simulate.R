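#' Configuration for a single synthetic power spectrum
#'
#' Describes the generative model the estimation pipeline inverts: an
#' aperiodic power law with multiplicative log-power noise, times a Gaussian
#' alpha bump on the detrended (exponentiated-residual) scale,
#' \deqn{P(f) = 10^{\,\mathrm{offset} - \mathrm{exponent}\cdot\log_{10} f + \varepsilon(f)}
#'   \left(1 + a\, e^{-(f-\mu)^2 / 2\sigma^2}\right),\quad
#'   \varepsilon \sim N(0, \mathrm{noise\_sd}^2).}
#' `peak_amplitude` is therefore the bump height relative to the local
#' aperiodic level (a flat background at power 1 with amplitude 0.5 reaches
#' 1.5 at the peak), which is exactly the quantity the Gaussian stage of the
#' estimator fits, so noiseless spectra are recovered exactly.
#'
#' @param aperiodic_offset log10-power at 1 Hz.
#' @param aperiodic_exponent 1/f slope magnitude, `>= 0`.
#' @param peak_amplitude Relative bump height, `>= 0` (0 = no alpha peak).
#' @param peak_center Peak frequency in Hz.
#' @param peak_width Gaussian sigma in Hz, `> 0`.
#' @param noise_sd SD of the multiplicative log10-power noise, `>= 0`.
#' @param freq_min,freq_max,freq_step Frequency grid in Hz;
#'   `0 < freq_min < freq_max`, `freq_step > 0`.
#'
#' @return An object of class `spectrum_sim_config`.
#' @export
spectrum_sim_config <- function(aperiodic_offset = 0, aperiodic_exponent = 1,
                                peak_amplitude = 0.5, peak_center = 10,
                                peak_width = 1, noise_sd = 0.05,
                                freq_min = 1, freq_max = 55, freq_step = 0.2) {
  ok <- is_number(aperiodic_offset) && is_number(aperiodic_exponent) &&
    aperiodic_exponent >= 0 && is_number(peak_amplitude) && peak_amplitude >= 0 &&
    is_number(peak_center) && peak_center > 0 && is_number(peak_width) &&
    peak_width > 0 && is_number(noise_sd) && noise_sd >= 0 &&
    is_number(freq_min) && freq_min > 0 && is_number(freq_step) && freq_step > 0 &&
    is_number(freq_max) && freq_min < freq_max
  if (!ok) {
    stop_alphapaf("invalid spectrum simulation configuration",
                  "alphapaf_config_error")
  }
  structure(as.list(environment())[c(
    "aperiodic_offset", "aperiodic_exponent", "peak_amplitude", "peak_center",
    "peak_width", "noise_sd", "freq_min", "freq_max", "freq_step")],
    class = "spectrum_sim_config")
}

sim_freq_grid <- function(config) {
  seq(config$freq_min, config$freq_max, by = config$freq_step)
}

sim_power <- function(config, freqs, eps = 0, center = config$peak_center,
                      amplitude = config$peak_amplitude) {
  10^(config$aperiodic_offset - config$aperiodic_exponent * log10(freqs) + eps) *
    (1 + amplitude * exp(-(freqs - center)^2 / (2 * config$peak_width^2)))
}

#' Simulate one power spectrum
#'
#' Draws a spectrum from the generative model of [spectrum_sim_config()].
#' Identical config and seed give bit-identical output; power is strictly
#' positive by construction.
#'
#' @param config A [spectrum_sim_config()].
#' @param seed Integer seed.
#' @param subject_id,parcel Identifiers attached to the output.
#'
#' @return A [power_spectrum()].
#' @export
simulate_spectrum <- function(config, seed = 1,
                              subject_id = NA_character_,
                              parcel = NA_character_) {
  stopifnot(inherits(config, "spectrum_sim_config"))
  freqs <- sim_freq_grid(config)
  eps <- if (config$noise_sd > 0) {
    set.seed(seed)
    stats::rnorm(length(freqs), 0, config$noise_sd)
  } else 0
  power_spectrum(freqs, sim_power(config, freqs, eps),
                 subject_id = subject_id, parcel = parcel)
}

#' Simulate a time series with a prescribed spectrum
#'
#' Generates colored noise by spectral shaping: complex Gaussian Fourier
#' coefficients are scaled so the expected one-sided PSD equals the
#' configured aperiodic law times the alpha bump, then inverse-transformed to
#' a real series. The alpha oscillation thus appears as a band-limited
#' stochastic rhythm at `peak_center`, not a deterministic sinusoid; set
#' `noise_sd` has no role here (the series is stochastic by construction).
#'
#' @param config A [spectrum_sim_config()] (its frequency grid is ignored;
#'   the spectral shape is evaluated on the FFT grid).
#' @param duration_s Duration in seconds; `duration_s * fs` must be a
#'   positive whole number.
#' @param fs Sampling rate in Hz (default 500).
#' @param seed Integer seed.
#' @param subject_id,parcel Identifiers attached to the output.
#'
#' @return A [regional_timeseries()] of `duration_s * fs` samples.
#' @export
simulate_timeseries <- function(config, duration_s, fs = 500, seed = 1,
                                subject_id = NA_character_,
                                parcel = NA_character_) {
  stopifnot(inherits(config, "spectrum_sim_config"))
  if (!is_number(fs) || fs <= 0) {
    stop_alphapaf("`fs` must be positive", "alphapaf_config_error")
  }
  n <- duration_s * fs
  if (!is_number(n) || n <= 0 || abs(n - round(n)) > 1e-8) {
    stop_alphapaf("`duration_s * fs` must be a positive integer",
                  "alphapaf_config_error")
  }
  n <- as.integer(round(n))
  freqs <- seq.int(0L, n %/% 2L) * (fs / n)
  shape <- numeric(length(freqs))
  pos <- freqs > 0
  shape[pos] <- sim_power(config, freqs[pos])
  shape[1L] <- 0  # no DC power
  set.seed(seed)
  n_half <- length(freqs)
  re <- stats::rnorm(n_half)
  im <- stats::rnorm(n_half)
  # E|X_k|^2 = S(f_k) * fs * n / 2 reproduces S as the one-sided density
  amp <- sqrt(shape * fs * n / 2)
  X <- complex(real = re, imaginary = im) * amp / sqrt(2)
  X[1L] <- 0
  if (n %% 2L == 0L) X[n_half] <- re[n_half] * sqrt(shape[n_half] * fs * n / 2)
  full <- complex(length.out = n)
  full[seq_len(n_half)] <- X
  if (n %% 2L == 0L) {
    full[seq.int(n_half + 1L, n)] <- Conj(X[seq.int(n_half - 1L, 2L)])
  } else {
    full[seq.int(n_half + 1L, n)] <- Conj(X[seq.int(n_half, 2L)])
  }
  x <- Re(stats::fft(full, inverse = TRUE)) / n
  regional_timeseries(x, fs = fs, subject_id = subject_id, parcel = parcel)
}

#' Configuration for a synthetic two-group cohort
#'
#' Defaults encode the study conditions of an ASD versus typically developing
#' (TD) comparison in 5-7-year-olds: 19 ASD and 24 TD children, ages uniform
#' over 60-89 and 60-91 months, SRS total t-scores 67.6 (SD 14.3) versus 46.4
#' (SD 6.4), K-ABC MPS 103.1 (16.7) versus 115.4 (12.4) and ACH 98.0 (17.8)
#' versus 107.4 (13.7), male fractions 13/19 and 14/24. Each subject carries
#' 68 Desikan-Killiany parcel spectra whose true peak centers are
#' `paf_baseline[region] + age_slope[region, group] * (age - group mean age)
#' + subject effect + parcel jitter`; a per-group fraction of parcels has no
#' alpha peak at all (amplitude 0). The default age slope places the
#' diagnosis-age interaction of 0.053 Hz/month in the two cingulate regions
#' (ASD only), and the default noise scales (`subject_sd` 0.45 Hz,
#' `parcel_sd` 0.3 Hz) reproduce regional regression residuals of about
#' 0.46 Hz.
#'
#' @param n_asd,n_td Group sizes.
#' @param age_range_asd,age_range_td Age intervals in months.
#' @param p_male_asd,p_male_td Male fractions.
#' @param srs_mean,srs_sd,mps_mean,mps_sd,ach_mean,ach_sd Named numeric
#'   vectors `c(ASD = , TD = )` of trait-score means and SDs. SRS subscale
#'   t-scores are drawn around the same group mean.
#' @param paf_baseline Named vector over [region_labels()] of baseline PAFs
#'   in Hz (unassigned parcels use their hemisphere's mean baseline).
#' @param age_slope Named-list or matrix of Hz/month slopes per region and
#'   group; see [default_age_slopes()].
#' @param subject_sd Between-subject PAF SD in Hz, shared across parcels.
#' @param parcel_sd Within-subject between-parcel PAF jitter SD in Hz.
#' @param invalid_peak_rate Probability a parcel has no alpha peak; scalar or
#'   named vector `c(ASD = , TD = )`.
#' @param spectrum Template [spectrum_sim_config()] for per-parcel spectra
#'   (its `peak_center` is overridden by each parcel's true PAF).
#' @param seed Integer seed.
#'
#' @return An object of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n_asd = 19, n_td = 24,
                              age_range_asd = c(60, 89),
                              age_range_td = c(60, 91),
                              p_male_asd = 13 / 19, p_male_td = 14 / 24,
                              srs_mean = c(ASD = 67.6, TD = 46.4),
                              srs_sd = c(ASD = 14.3, TD = 6.4),
                              mps_mean = c(ASD = 103.1, TD = 115.4),
                              mps_sd = c(ASD = 16.7, TD = 12.4),
                              ach_mean = c(ASD = 98.0, TD = 107.4),
                              ach_sd = c(ASD = 17.8, TD = 13.7),
                              paf_baseline = default_paf_baseline(),
                              age_slope = default_age_slopes(),
                              subject_sd = 0.45, parcel_sd = 0.3,
                              invalid_peak_rate = c(ASD = 0.05, TD = 0.02),
                              spectrum = spectrum_sim_config(),
                              seed = 1L) {
  if (!is_count(n_asd) || !is_count(n_td)) {
    stop_alphapaf("group sizes must be positive integers", "alphapaf_config_error")
  }
  sds <- c(srs_sd, mps_sd, ach_sd, subject_sd, parcel_sd)
  if (any(sds < 0)) {
    stop_alphapaf("standard deviations must be >= 0", "alphapaf_config_error")
  }
  rate <- expand_group(invalid_peak_rate)
  if (any(rate < 0 | rate > 1)) {
    stop_alphapaf("`invalid_peak_rate` must be in [0, 1]", "alphapaf_config_error")
  }
  bad <- setdiff(names(paf_baseline), region_labels())
  if (length(bad) || !all(region_labels() %in% names(paf_baseline))) {
    stop_alphapaf(sprintf("`paf_baseline` must be named by the 10 region labels%s",
                          if (length(bad)) paste0("; unknown: ",
                                                  paste(bad, collapse = ", ")) else ""),
                  "alphapaf_config_error")
  }
  slope <- as_slope_matrix(age_slope)
  structure(
    list(n_asd = n_asd, n_td = n_td,
         age_range_asd = age_range_asd, age_range_td = age_range_td,
         p_male_asd = p_male_asd, p_male_td = p_male_td,
         srs_mean = expand_group(srs_mean), srs_sd = expand_group(srs_sd),
         mps_mean = expand_group(mps_mean), mps_sd = expand_group(mps_sd),
         ach_mean = expand_group(ach_mean), ach_sd = expand_group(ach_sd),
         paf_baseline = paf_baseline, age_slope = slope,
         subject_sd = subject_sd, parcel_sd = parcel_sd,
         invalid_peak_rate = rate, spectrum = spectrum, seed = as.integer(seed)),
    class = "cohort_sim_config"
  )
}

expand_group <- function(x) {
  if (length(x) == 1L && is.null(names(x))) x <- c(ASD = unname(x), TD = unname(x))
  if (!all(c("ASD", "TD") %in% names(x))) {
    stop_alphapaf("group-wise parameters must be named c(ASD=, TD=)",
                  "alphapaf_config_error")
  }
  x[c("ASD", "TD")]
}

as_slope_matrix <- function(age_slope) {
  m <- matrix(0, nrow = 10, ncol = 2,
              dimnames = list(region_labels(), c("ASD", "TD")))
  if (is.matrix(age_slope)) {
    bad <- setdiff(rownames(age_slope), region_labels())
    if (length(bad)) {
      stop_alphapaf(sprintf("unknown region labels in `age_slope`: %s",
                            paste(bad, collapse = ", ")),
                    "alphapaf_config_error")
    }
    m[rownames(age_slope), colnames(age_slope)] <- age_slope
  } else if (is.list(age_slope)) {
    for (g in names(age_slope)) {
      v <- age_slope[[g]]
      bad <- setdiff(names(v), region_labels())
      if (length(bad)) {
        stop_alphapaf(sprintf("unknown region labels in `age_slope`: %s",
                              paste(bad, collapse = ", ")),
                      "alphapaf_config_error")
      }
      m[names(v), g] <- v
    }
  } else {
    stop_alphapaf("`age_slope` must be a matrix or named list", "alphapaf_config_error")
  }
  m
}

#' Default regional PAF baselines (Hz)
#'
#' Child-typical values around 9 Hz, slightly lower in occipital and
#' temporal regions.
#'
#' @return Named vector over [region_labels()].
#' @export
default_paf_baseline <- function() {
  b <- c(cingulate = 9.2, frontal = 9.0, occipital = 8.8, parietal = 9.1,
         temporal = 8.9)
  out <- stats::setNames(numeric(10), region_labels())
  for (r in region_labels()) {
    out[r] <- b[sub("^(left|right)_", "", r)]
  }
  out
}

#' Default diagnosis-specific age slopes (Hz/month)
#'
#' An ASD-only slope of 0.053 Hz/month in both cingulate regions, zero
#' elsewhere, i.e. a diagnosis-age interaction of 0.053 confined to the
#' cingulate.
#'
#' @return Named list with elements `ASD` and `TD`.
#' @export
default_age_slopes <- function() {
  list(ASD = c(left_cingulate = 0.053, right_cingulate = 0.053))
}

parcel_region <- function(mapping = dk_region_mapping()) {
  reg <- mapping$region
  # unassigned parcels still get a true PAF: use the hemisphere mean baseline
  names(reg) <- mapping$parcel
  reg
}

#' Simulate a two-group cohort of subjects and parcel spectra
#'
#' Draws subject metadata (diagnosis, sex, age, SRS total and five subscale
#' t-scores, K-ABC MPS and ACH) and, for each subject, the true alpha-peak
#' center of each of the 68 Desikan-Killiany parcels:
#' `baseline[region] + age_slope[region, group] * (age - group mean age) +
#' subject effect + parcel jitter`, with a per-group fraction of parcels
#' carrying no peak (amplitude 0). With `spectra = TRUE` each parcel also
#' gets a simulated power spectrum from the template generator, so the full
#' estimation pipeline can run end to end; with `spectra = FALSE` only the
#' truth table is returned (useful for statistical Monte Carlo at scale).
#'
#' @param config A [cohort_sim_config()].
#' @param spectra Generate per-parcel spectra (default `TRUE`).
#'
#' @return List with elements `metadata` (one row per subject),
#'   `parcel_truth` (subject x parcel truth: `true_paf`, `has_peak`,
#'   `region`), and `spectra` (long data frame `subject_id`, `parcel`,
#'   `freq_hz`, `power`, or `NULL`).
#' @export
simulate_cohort <- function(config, spectra = TRUE) {
  stopifnot(inherits(config, "cohort_sim_config"))
  set.seed(config$seed)
  n <- config$n_asd + config$n_td
  diagnosis <- c(rep("ASD", config$n_asd), rep("TD", config$n_td))
  ids <- sprintf("S%03d", seq_len(n))
  age <- numeric(n)
  sex <- character(n)
  draw_group <- function(grp, mean, sd) {
    stats::rnorm(sum(diagnosis == grp), mean[grp], sd[grp])
  }
  for (grp in c("ASD", "TD")) {
    sel <- diagnosis == grp
    rng <- if (grp == "ASD") config$age_range_asd else config$age_range_td
    pm <- if (grp == "ASD") config$p_male_asd else config$p_male_td
    age[sel] <- round(stats::runif(sum(sel), rng[1], rng[2]))
    sex[sel] <- ifelse(stats::runif(sum(sel)) < pm, "M", "F")
  }
  md <- data.frame(subject_id = ids, group = diagnosis, sex = sex,
                   age_months = age, stringsAsFactors = FALSE)
  for (col in c("srs_total", "srs_awareness", "srs_cognition",
                "srs_communication", "srs_motivation", "srs_mannerism")) {
    md[[col]] <- NA_real_
  }
  md$mps <- NA_real_
  md$ach <- NA_real_
  for (grp in c("ASD", "TD")) {
    sel <- diagnosis == grp
    md$srs_total[sel] <- stats::rnorm(sum(sel), config$srs_mean[grp], config$srs_sd[grp])
    for (sub in c("srs_awareness", "srs_cognition", "srs_communication",
                  "srs_motivation", "srs_mannerism")) {
      md[[sub]][sel] <- stats::rnorm(sum(sel), config$srs_mean[grp], config$srs_sd[grp])
    }
    md$mps[sel] <- stats::rnorm(sum(sel), config$mps_mean[grp], config$mps_sd[grp])
    md$ach[sel] <- stats::rnorm(sum(sel), config$ach_mean[grp], config$ach_sd[grp])
  }
  mapping <- dk_region_mapping()
  n_parcel <- nrow(mapping)
  subj_eff <- stats::rnorm(n, 0, config$subject_sd)
  mean_age <- c(ASD = mean(config$age_range_asd), TD = mean(config$age_range_td))
  hemi_base <- c(left = mean(config$paf_baseline[grep("^left_", region_labels())]),
                 right = mean(config$paf_baseline[grep("^right_", region_labels())]))
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    grp <- diagnosis[i]
    base <- ifelse(is.na(mapping$region),
                   hemi_base[mapping$hemisphere],
                   config$paf_baseline[mapping$region])
    slope <- ifelse(is.na(mapping$region), 0,
                    config$age_slope[ifelse(is.na(mapping$region),
                                            "left_cingulate", mapping$region), grp])
    true_paf <- base + slope * (age[i] - mean_age[grp]) + subj_eff[i] +
      stats::rnorm(n_parcel, 0, config$parcel_sd)
    has_peak <- stats::runif(n_parcel) >= config$invalid_peak_rate[grp]
    truth[[i]] <- data.frame(
      subject_id = ids[i], parcel = mapping$parcel, region = mapping$region,
      true_paf = unname(true_paf), has_peak = has_peak,
      stringsAsFactors = FALSE
    )
  }
  parcel_truth <- do.call(rbind, truth)
  rownames(parcel_truth) <- NULL
  spectra_df <- NULL
  if (spectra) {
    freqs <- sim_freq_grid(config$spectrum)
    n_bin <- length(freqs)
    blocks <- vector("list", nrow(parcel_truth))
    for (j in seq_len(nrow(parcel_truth))) {
      eps <- if (config$spectrum$noise_sd > 0) {
        stats::rnorm(n_bin, 0, config$spectrum$noise_sd)
      } else 0
      amp <- if (parcel_truth$has_peak[j]) config$spectrum$peak_amplitude else 0
      blocks[[j]] <- sim_power(config$spectrum, freqs, eps,
                               center = parcel_truth$true_paf[j],
                               amplitude = amp)
    }
    spectra_df <- data.frame(
      subject_id = rep(parcel_truth$subject_id, each = n_bin),
      parcel = rep(parcel_truth$parcel, each = n_bin),
      freq_hz = rep(freqs, times = nrow(parcel_truth)),
      power = unlist(blocks, use.names = FALSE),
      stringsAsFactors = FALSE
    )
  }
  list(metadata = md, parcel_truth = parcel_truth, spectra = spectra_df)
}

#' Write a simulated cohort to CSV files
#'
#' Writes `metadata.csv`, `parcel_truth.csv` and (when present)
#' `spectra.csv` into `dir`.
#'
#' @param cohort Result of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#'
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$metadata, file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$parcel_truth, file.path(dir, "parcel_truth.csv"),
                   row.names = FALSE)
  if (!is.null(cohort$spectra)) {
    utils::write.csv(cohort$spectra, file.path(dir, "spectra.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}
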