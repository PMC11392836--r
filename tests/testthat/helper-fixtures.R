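# Fixtures built in code; every helper is deterministic given its arguments.

default_grid <- function() seq(1, 55, by = 0.2)

# Spectrum that is exactly a power law times a Gaussian alpha bump, no noise.
clean_spectrum <- function(exponent = 2, offset = 0, amplitude = 0.5,
                           center = 10, width = 1, freqs = default_grid()) {
  power_spectrum(
    freqs,
    10^(offset - exponent * log10(freqs)) *
      (1 + amplitude * exp(-(freqs - center)^2 / (2 * width^2)))
  )
}

# Long spectra table for a toy set of subjects x parcels.
toy_spectra_table <- function(subjects, parcels, centers) {
  rows <- list()
  for (i in seq_along(subjects)) {
    for (j in seq_along(parcels)) {
      s <- clean_spectrum(exponent = 1, center = centers[[i]][[j]])
      rows[[paste(i, j)]] <- data.frame(
        subject_id = subjects[i], parcel = parcels[j],
        freq_hz = s$freqs, power = s$power, stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

# Parcel-fit table in the shape estimate_paf_table() produces.
toy_parcel_fits <- function(subject_id, parcels, paf, valid,
                            rel_alpha = NA_real_) {
  data.frame(subject_id = subject_id, parcel = parcels, paf_hz = paf,
             amplitude = NA_real_, width_hz = NA_real_, valid = valid,
             reject_reason = ifelse(valid, NA_character_, "outside_band"),
             aperiodic_slope = NA_real_, aperiodic_intercept = NA_real_,
             rel_alpha = rel_alpha, stringsAsFactors = FALSE)
}

# Region-level PAF table with a known linear generative model, for the
# statistics layer: paf = b0 + b_dx * dx + b_age * age + b_int * dx * age
# (+ noise), one row per subject x region.
toy_region_table <- function(metadata, b0 = 9, b_dx = 0, b_age = 0,
                             b_int = 0, sd = 0, regions = region_labels(),
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(regions, function(r) {
    dx <- ifelse(metadata$group == "ASD", 1, 0)
    mu <- b0 + b_dx * dx + b_age * metadata$age_months +
      b_int * dx * metadata$age_months
    data.frame(subject_id = metadata$subject_id, region = r,
               paf_hz = mu + if (sd > 0) rnorm(nrow(metadata), 0, sd) else 0,
               n_valid_parcels = 4L, n_total_parcels = 4L,
               rel_alpha = NA_real_, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

toy_metadata <- function(n_asd = 19, n_td = 24, seed = 1) {
  set.seed(seed)
  n <- n_asd + n_td
  data.frame(
    subject_id = sprintf("S%03d", seq_len(n)),
    group = c(rep("ASD", n_asd), rep("TD", n_td)),
    sex = sample(c("M", "F"), n, replace = TRUE),
    age_months = c(round(runif(n_asd, 60, 89)), round(runif(n_td, 60, 91))),
    srs_total = c(rnorm(n_asd, 67.6, 14.3), rnorm(n_td, 46.4, 6.4)),
    srs_awareness = rnorm(n, 55, 10), srs_cognition = rnorm(n, 55, 10),
    srs_communication = rnorm(n, 55, 10), srs_motivation = rnorm(n, 55, 10),
    srs_mannerism = rnorm(n, 55, 10),
    mps = c(rnorm(n_asd, 103.1, 16.7), rnorm(n_td, 115.4, 12.4)),
    ach = c(rnorm(n_asd, 98.0, 17.8), rnorm(n_td, 107.4, 13.7)),
    stringsAsFactors = FALSE
  )
}

# Brute-force Benjamini-Hochberg step-up rule, straight from the definition.
bh_bruteforce <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  ks <- which(ps <= seq_len(m) * q / m)
  reject <- logical(m)
  if (length(ks)) reject[ord[seq_len(max(ks))]] <- TRUE
  reject
}

# Dense grid search oracle for the Gaussian peak fit (baseline fixed at 1):
# amplitude solved in closed form per (mu, sigma) candidate.
gaussian_gridsearch <- function(f, y, mu_grid = seq(5, 15, by = 0.01),
                                sigma_grid = seq(0.2, 3, by = 0.02)) {
  best <- c(sse = Inf, a = NA, mu = NA, s = NA)
  for (s in sigma_grid) {
    for (mu in mu_grid) {
      g <- exp(-(f - mu)^2 / (2 * s^2))
      a <- max(0, sum((y - 1) * g) / sum(g^2))
      sse <- sum((y - 1 - a * g)^2)
      if (sse < best["sse"]) best <- c(sse = sse, a = a, mu = mu, s = s)
    }
  }
  best
}
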