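#' Frequency-band configuration for PAF estimation
#'
#' @param fit_range Hz interval over which the aperiodic 1/f trend is fitted
#'   (default 1-55 Hz).
#' @param alpha_band Hz interval in which a valid alpha peak must lie
#'   (default 7-13 Hz); must be nested inside `fit_range`.
#'
#' @return An object of class `band_config`.
#' @export
band_config <- function(fit_range = c(1, 55), alpha_band = c(7, 13)) {
  stopifnot(length(fit_range) == 2L, length(alpha_band) == 2L)
  if (!(fit_range[1] < fit_range[2]) || !(alpha_band[1] < alpha_band[2])) {
    stop_alphapaf("band lower bounds must be below upper bounds",
                  "alphapaf_config_error")
  }
  if (alpha_band[1] < fit_range[1] || alpha_band[2] > fit_range[2]) {
    stop_alphapaf("`alpha_band` must be nested inside `fit_range`",
                  "alphapaf_config_error")
  }
  structure(list(fit_range = as.numeric(fit_range),
                 alpha_band = as.numeric(alpha_band)),
            class = "band_config")
}

#' Robust fit of the aperiodic 1/f component
#'
#' Regresses log10(power) on log10(frequency) over `fit_range` by iteratively
#' reweighted least squares under the Huber loss (tuning constant 1.35 on
#' MAD-standardized residuals), so that narrow-band peaks such as the alpha
#' bump are down-weighted and the broadband power-law trend is recovered.
#' Zero or negative power bins are floored at 1e-6 times the smallest
#' positive bin before the log transform.
#'
#' @param spec A [power_spectrum()].
#' @param cfg A [band_config()].
#' @param tuning_constant Huber threshold in standardized-residual units
#'   (default 1.35).
#'
#' @return An object of class `aperiodic_fit` with fields `intercept`
#'   (log10 power at log10 f = 0), `slope`, `tuning_constant`,
#'   `n_iterations`, `converged`.
#' @export
fit_aperiodic <- function(spec, cfg = band_config(), tuning_constant = 1.35) {
  stopifnot(inherits(spec, "power_spectrum"), inherits(cfg, "band_config"))
  keep <- in_band(spec$freqs, cfg$fit_range)
  if (sum(keep) < 3L) {
    stop_alphapaf("fewer than 3 bins inside `fit_range`", "alphapaf_config_error")
  }
  f <- spec$freqs[keep]
  p <- spec$power[keep]
  pos <- p[p > 0]
  if (length(pos) == 0L) {
    stop_alphapaf("no positive power in `fit_range`", "alphapaf_config_error")
  }
  p[p <= 0] <- min(pos) * 1e-6
  lf <- log10(f)
  lp <- log10(p)
  converged <- TRUE
  fit <- withCallingHandlers(
    MASS::rlm(x = cbind(`(Intercept)` = 1, log10_f = lf), y = lp,
              psi = MASS::psi.huber, k = tuning_constant,
              scale.est = "MAD", maxit = 200, acc = 1e-8),
    warning = function(w) {
      if (grepl("failed to converge", conditionMessage(w))) {
        converged <<- FALSE
        invokeRestart("muffleWarning")
      }
    }
  )
  if (!isTRUE(fit$converged)) converged <- FALSE
  # a perfectly linear log-log spectrum drives the robust scale to zero and
  # defeats the relative convergence test; residuals at rounding error are
  # a converged fit by any reasonable standard
  if (!converged &&
      max(abs(fit$residuals)) < 1e-10 * max(1, max(abs(lp)))) {
    converged <- TRUE
  }
  structure(
    list(intercept = unname(stats::coef(fit)[1L]), slope = unname(stats::coef(fit)[2L]),
         tuning_constant = tuning_constant,
         n_iterations = length(fit$conv) %||% NA_integer_,
         converged = converged),
    class = "aperiodic_fit"
  )
}

#' @export
print.aperiodic_fit <- function(x, ...) {
  cat(sprintf("<aperiodic_fit> intercept=%.4f slope=%.4f (Huber k=%.2f, %s)\n",
              x$intercept, x$slope, x$tuning_constant,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Remove the fitted 1/f trend in log space
#'
#' @param spec A [power_spectrum()].
#' @param fit An [fit_aperiodic()] result; must have converged.
#' @param cfg A [band_config()]; residuals are returned over its `fit_range`.
#'
#' @return Data frame with columns `freq_hz` and `residual`, where
#'   `residual = log10 power - (intercept + slope * log10 freq)`.
#' @export
detrend_spectrum <- function(spec, fit, cfg = band_config()) {
  stopifnot(inherits(spec, "power_spectrum"), inherits(fit, "aperiodic_fit"))
  if (!fit$converged) {
    stop_alphapaf("aperiodic fit did not converge", "alphapaf_fit_error")
  }
  keep <- in_band(spec$freqs, cfg$fit_range)
  f <- spec$freqs[keep]
  p <- spec$power[keep]
  pos <- p[p > 0]
  p[p <= 0] <- min(pos) * 1e-6
  data.frame(freq_hz = f,
             residual = log10(p) - (fit$intercept + fit$slope * log10(f)))
}

#' Isolate and exponentiate the alpha-band residual
#'
#' Restricts the detrended spectrum to the alpha band (endpoints inclusive on
#' the discrete grid) and undoes the log transform, so that a flat detrended
#' spectrum sits at 1 and a peak rises above it.
#'
#' @param residual Data frame from [detrend_spectrum()].
#' @param cfg A [band_config()].
#'
#' @return Data frame with columns `freq_hz` and `value` (= 10^residual).
#' @export
isolate_alpha <- function(residual, cfg = band_config()) {
  stopifnot(is.data.frame(residual), all(c("freq_hz", "residual") %in% names(residual)))
  keep <- in_band(residual$freq_hz, cfg$alpha_band)
  if (!any(keep)) {
    stop_alphapaf("no frequency bins inside `alpha_band`",
                  "alphapaf_empty_residual")
  }
  data.frame(freq_hz = residual$freq_hz[keep],
             value = 10^residual$residual[keep])
}

new_alpha_peak_fit <- function(amplitude = NA_real_, center = NA_real_,
                               width = NA_real_, valid = FALSE,
                               reject_reason = NA_character_,
                               aperiodic = NULL) {
  structure(
    list(amplitude = amplitude, center = center, width = width,
         valid = valid, reject_reason = reject_reason, aperiodic = aperiodic),
    class = "alpha_peak_fit"
  )
}

#' @export
print.alpha_peak_fit <- function(x, ...) {
  if (x$valid) {
    cat(sprintf("<alpha_peak_fit> PAF=%.3f Hz (amplitude=%.3f, width=%.3f Hz)\n",
                x$center, x$amplitude, x$width))
  } else {
    cat(sprintf("<alpha_peak_fit> invalid (%s)\n", x$reject_reason))
  }
  invisible(x)
}

#' Gaussian parameterization of the alpha-band residual
#'
#' Fits `a * exp(-(f - mu)^2 / (2 sigma^2)) + baseline` to the exponentiated
#' alpha-band residual by bounded least squares. The baseline is fixed at 1
#' by default (the null level of an exponentiated log residual); `baseline =
#' "free"` fits an additive offset instead. The center is initialized at the
#' band argmax and allowed to travel beyond the alpha band (mu in [5, 15]):
#' a fit whose vertex lands outside the band, fails to converge, or carries
#' non-positive amplitude is marked invalid with a `reject_reason` in
#' `outside_band`, `no_convergence`, `non_positive_amplitude`,
#' `empty_residual`.
#'
#' @param band_residual Data frame from [isolate_alpha()].
#' @param alpha_band Hz interval a valid vertex must lie in (default 7-13).
#' @param baseline `"fixed1"` (default) or `"free"`.
#'
#' @return An object of class `alpha_peak_fit` with fields `amplitude`,
#'   `center` (the PAF, Hz), `width` (Gaussian sigma, Hz), `valid`,
#'   `reject_reason`.
#' @export
fit_gaussian_peak <- function(band_residual, alpha_band = c(7, 13),
                              baseline = c("fixed1", "free")) {
  baseline <- match.arg(baseline)
  stopifnot(is.data.frame(band_residual),
            all(c("freq_hz", "value") %in% names(band_residual)))
  f <- band_residual$freq_hz
  y <- band_residual$value
  if (length(f) == 0L) {
    return(new_alpha_peak_fit(reject_reason = "empty_residual"))
  }
  if (length(f) < 4L) {
    stop_alphapaf("at least 4 bins required for the Gaussian fit",
                  "alphapaf_config_error")
  }
  mu0 <- f[which.max(y)]
  base0 <- if (baseline == "fixed1") 1 else min(y)
  a0 <- max(max(y) - base0, 1e-3)
  ctrl <- minpack.lm::nls.lm.control(maxiter = 200)
  fit <- tryCatch({
    if (baseline == "fixed1") {
      minpack.lm::nlsLM(
        y ~ a * exp(-(f - mu)^2 / (2 * s^2)) + 1,
        start = list(a = a0, mu = mu0, s = 1),
        lower = c(0, 5, 0.1), upper = c(Inf, 15, 6), control = ctrl)
    } else {
      minpack.lm::nlsLM(
        y ~ a * exp(-(f - mu)^2 / (2 * s^2)) + b,
        start = list(a = a0, mu = mu0, s = 1, b = base0),
        lower = c(0, 5, 0.1, -Inf), upper = c(Inf, 15, 6, Inf), control = ctrl)
    }
  }, error = function(e) NULL)
  if (is.null(fit)) {
    return(new_alpha_peak_fit(reject_reason = "no_convergence"))
  }
  cf <- stats::coef(fit)
  out <- new_alpha_peak_fit(amplitude = unname(cf["a"]),
                            center = unname(cf["mu"]),
                            width = unname(cf["s"]))
  if (!all(is.finite(cf))) {
    out$reject_reason <- "no_convergence"
  } else if (cf["a"] <= 1e-8) {
    out$reject_reason <- "non_positive_amplitude"
  } else if (cf["mu"] < alpha_band[1] - 1e-9 || cf["mu"] > alpha_band[2] + 1e-9) {
    out$reject_reason <- "outside_band"
  } else {
    out$valid <- TRUE
  }
  out
}

#' Estimate the peak alpha frequency of one spectrum
#'
#' End-to-end composition of the PAF algorithm: robust 1/f fit in log-log
#' space over `fit_range`, subtraction of the fitted trend, exponentiation,
#' restriction to the alpha band, and bounded Gaussian least squares. The
#' vertex of the fitted Gaussian is the PAF; fits whose vertex falls outside
#' the alpha band (or that fail) are flagged invalid, signalling the absence
#' of a distinct alpha peak. Deterministic given its input.
#'
#' @inheritParams fit_aperiodic
#' @inheritParams fit_gaussian_peak
#'
#' @return An `alpha_peak_fit`; its `aperiodic` field carries the 1/f fit.
#' @export
estimate_paf <- function(spec, cfg = band_config(), tuning_constant = 1.35,
                         baseline = "fixed1") {
  ap <- fit_aperiodic(spec, cfg, tuning_constant)
  if (!ap$converged) {
    out <- new_alpha_peak_fit(reject_reason = "no_convergence", aperiodic = ap)
    return(out)
  }
  res <- detrend_spectrum(spec, ap, cfg)
  band <- tryCatch(isolate_alpha(res, cfg), alphapaf_empty_residual = function(e) NULL)
  if (is.null(band)) {
    return(new_alpha_peak_fit(reject_reason = "empty_residual", aperiodic = ap))
  }
  out <- fit_gaussian_peak(band, alpha_band = cfg$alpha_band, baseline = baseline)
  out$aperiodic <- ap
  out
}

#' Estimate PAFs for a long table of spectra
#'
#' Applies [estimate_paf()] to every subject-by-parcel spectrum in a long
#' data frame and returns one row per parcel, the format consumed by
#' [aggregate_regions()].
#'
#' @param spectra Data frame with columns `subject_id`, `parcel`, `freq_hz`,
#'   `power` (one row per frequency bin).
#' @inheritParams estimate_paf
#' @param alpha_band,total_band Bands for [relative_alpha_power()], computed
#'   per parcel alongside the PAF.
#'
#' @return Data frame with columns `subject_id`, `parcel`, `paf_hz`,
#'   `amplitude`, `width_hz`, `valid`, `reject_reason`, `aperiodic_slope`,
#'   `aperiodic_intercept`, `rel_alpha`.
#' @export
estimate_paf_table <- function(spectra, cfg = band_config(),
                               tuning_constant = 1.35, baseline = "fixed1",
                               alpha_band = cfg$alpha_band,
                               total_band = cfg$fit_range) {
  stopifnot(all(c("subject_id", "parcel", "freq_hz", "power") %in% names(spectra)))
  keys <- unique(spectra[, c("subject_id", "parcel")])
  idx <- split(seq_len(nrow(spectra)),
               paste(spectra$subject_id, spectra$parcel, sep = "\r"))
  rows <- lapply(idx, function(i) {
    block <- spectra[i, ]
    ord <- order(block$freq_hz)
    spec <- power_spectrum(block$freq_hz[ord], block$power[ord],
                           subject_id = block$subject_id[1L],
                           parcel = block$parcel[1L])
    fit <- estimate_paf(spec, cfg, tuning_constant, baseline)
    data.frame(
      subject_id = spec$subject_id, parcel = spec$parcel,
      paf_hz = if (fit$valid) fit$center else NA_real_,
      amplitude = fit$amplitude, width_hz = fit$width,
      valid = fit$valid, reject_reason = fit$reject_reason,
      aperiodic_slope = if (is.null(fit$aperiodic)) NA_real_ else fit$aperiodic$slope,
      aperiodic_intercept = if (is.null(fit$aperiodic)) NA_real_ else fit$aperiodic$intercept,
      rel_alpha = relative_alpha_power(spec, alpha_band, total_band),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  # restore input ordering of subject/parcel pairs
  key_in <- paste(keys$subject_id, keys$parcel, sep = "\r")
  out[match(key_in, paste(out$subject_id, out$parcel, sep = "\r")), , drop = FALSE]
}
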