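#' Regional source time series
#'
#' Container for one subject-by-parcel source-level time series, the unit of
#' input to the spectral stage. Sampling is assumed regular.
#'
#' @param samples Numeric vector of source amplitudes, in temporal order.
#' @param fs Sampling rate in Hz (default 500, the rate the pipeline assumes
#'   downstream defaults were chosen for).
#' @param subject_id,parcel Identifiers carried through the pipeline.
#'
#' @return An object of class `regional_timeseries`.
#' @export
regional_timeseries <- function(samples, fs = 500,
                                subject_id = NA_character_,
                                parcel = NA_character_) {
  if (!is_number(fs) || fs <= 0) {
    stop_alphapaf("`fs` must be a single positive number", "alphapaf_config_error")
  }
  samples <- as.numeric(samples)
  if (length(samples) < 1L || anyNA(samples)) {
    stop_alphapaf("`samples` must be a non-empty numeric vector without NAs",
                  "alphapaf_config_error")
  }
  structure(
    list(subject_id = as.character(subject_id), parcel = as.character(parcel),
         fs = fs, samples = samples),
    class = "regional_timeseries"
  )
}

#' Power spectrum for one subject-by-parcel signal
#'
#' @param freqs Strictly increasing frequency grid (Hz) with constant spacing.
#' @param power Non-negative power values, same length as `freqs`.
#' @param subject_id,parcel Identifiers carried through the pipeline.
#'
#' @return An object of class `power_spectrum`.
#' @export
power_spectrum <- function(freqs, power,
                           subject_id = NA_character_,
                           parcel = NA_character_) {
  freqs <- as.numeric(freqs)
  power <- as.numeric(power)
  if (length(freqs) != length(power) || length(freqs) < 1L) {
    stop_alphapaf("`freqs` and `power` must be non-empty and of equal length",
                  "alphapaf_config_error")
  }
  if (any(diff(freqs) <= 0)) {
    stop_alphapaf("`freqs` must be strictly increasing", "alphapaf_config_error")
  }
  if (length(freqs) > 2L) {
    steps <- diff(freqs)
    if (max(steps) - min(steps) > 1e-6 * max(steps)) {
      stop_alphapaf("`freqs` must have constant spacing", "alphapaf_config_error")
    }
  }
  if (any(!is.finite(power)) || any(power < 0)) {
    stop_alphapaf("`power` must be finite and non-negative", "alphapaf_config_error")
  }
  structure(
    list(subject_id = as.character(subject_id), parcel = as.character(parcel),
         freqs = freqs, power = power),
    class = "power_spectrum"
  )
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("<power_spectrum> subject=%s parcel=%s  %d bins, %.4g-%.4g Hz (step %.4g Hz)\n",
              x$subject_id, x$parcel, length(x$freqs),
              min(x$freqs), max(x$freqs), diff(x$freqs[1:2])))
  invisible(x)
}

#' Cut a recording into fixed-length segments
#'
#' Splits a continuous recording into consecutive non-overlapping segments of
#' `segment_len_s` seconds, dropping any trailing remainder. Subjects that do
#' not reach `min_segments` complete segments are rejected: an error of class
#' `alphapaf_subject_rejection` is signalled carrying the achieved count
#' (fields `n_achieved`, `n_required`), so a pipeline can exclude the subject
#' and continue.
#'
#' @param ts A [regional_timeseries()].
#' @param segment_len_s Segment length in seconds (default 5).
#' @param min_segments Minimum number of complete segments required
#'   (default 10, i.e. a 50-s recording at the defaults).
#'
#' @return A list of numeric vectors, each of `segment_len_s * fs` samples.
#' @export
segment_recording <- function(ts, segment_len_s = 5, min_segments = 10) {
  stopifnot(inherits(ts, "regional_timeseries"))
  if (!is_number(segment_len_s) || segment_len_s <= 0) {
    stop_alphapaf("`segment_len_s` must be positive", "alphapaf_config_error")
  }
  n_seg_samples <- round(segment_len_s * ts$fs)
  if (n_seg_samples < 1) {
    stop_alphapaf("segment length shorter than one sample", "alphapaf_config_error")
  }
  n_complete <- length(ts$samples) %/% n_seg_samples
  if (n_complete < min_segments) {
    stop_alphapaf(
      sprintf("subject %s: %d complete %g-s segments, %d required",
              ts$subject_id, n_complete, segment_len_s, min_segments),
      "alphapaf_subject_rejection",
      n_achieved = n_complete, n_required = min_segments,
      subject_id = ts$subject_id
    )
  }
  lapply(seq_len(n_complete), function(i) {
    ts$samples[((i - 1L) * n_seg_samples + 1L):(i * n_seg_samples)]
  })
}

# One-sided periodogram of a single tapered window, density scaling
# (power per Hz): P(f) = |FFT(w*x)|^2 * 2 / (fs * sum(w^2)), DC and Nyquist
# bins not doubled. The window mean is removed before tapering.
periodogram_window <- function(x, w, fs) {
  x <- (x - mean(x)) * w
  n <- length(x)
  X <- stats::fft(x)
  n_keep <- n %/% 2L + 1L
  p <- (Mod(X[seq_len(n_keep)])^2) / (fs * sum(w^2))
  scale2 <- rep(2, n_keep)
  scale2[1L] <- 1
  if (n %% 2L == 0L) scale2[n_keep] <- 1
  p * scale2
}

#' Welch power spectral density
#'
#' Averages one-sided periodograms of Hamming-tapered windows. The window
#' length equals the segment length, so a 5-s window at any sampling rate
#' gives a bin spacing of 1/5 = 0.2 Hz. By default the accepted segments are
#' treated as one continuous record and windows are slid across it with the
#' configured overlap (80% by default); with
#' `respect_segment_boundaries = TRUE` one periodogram per segment is
#' averaged instead, so no window straddles a segment junction.
#'
#' @param segments List of equal-length numeric vectors, e.g. from
#'   [segment_recording()].
#' @param fs Sampling rate in Hz.
#' @param overlap_fraction Fractional overlap between consecutive windows in
#'   `[0, 1)`; default 0.8.
#' @param respect_segment_boundaries If `TRUE`, average per-segment
#'   periodograms instead of sliding windows across the concatenated record.
#' @param subject_id,parcel Identifiers attached to the output.
#'
#' @return A [power_spectrum()] on the grid `seq(0, fs/2, by = fs/n_window)`.
#' @export
welch_psd <- function(segments, fs, overlap_fraction = 0.8,
                      respect_segment_boundaries = FALSE,
                      subject_id = NA_character_, parcel = NA_character_) {
  if (!is.list(segments) || length(segments) == 0L) {
    stop_alphapaf("`segments` must be a non-empty list", "alphapaf_config_error")
  }
  if (!is_number(fs) || fs <= 0) {
    stop_alphapaf("`fs` must be positive", "alphapaf_config_error")
  }
  if (!is_number(overlap_fraction) || overlap_fraction < 0 || overlap_fraction >= 1) {
    stop_alphapaf("`overlap_fraction` must be in [0, 1)", "alphapaf_config_error")
  }
  n_win <- length(segments[[1L]])
  if (any(vapply(segments, length, 1L) != n_win)) {
    stop_alphapaf("all segments must have equal length", "alphapaf_config_error")
  }
  w <- signal::hamming(n_win)
  if (respect_segment_boundaries) {
    windows <- segments
  } else {
    x <- unlist(segments, use.names = FALSE)
    step <- max(1L, round(n_win * (1 - overlap_fraction)))
    starts <- seq.int(1L, length(x) - n_win + 1L, by = step)
    windows <- lapply(starts, function(s) x[s:(s + n_win - 1L)])
  }
  p <- Reduce(`+`, lapply(windows, periodogram_window, w = w, fs = fs)) /
    length(windows)
  freqs <- seq.int(0L, n_win %/% 2L) * (fs / n_win)
  power_spectrum(freqs, p, subject_id = subject_id, parcel = parcel)
}

#' Relative alpha power
#'
#' Fraction of total spectral power lying in the alpha band: the sum of power
#' over bins with `alpha_band[1] <= f <= alpha_band[2]` divided by the sum
#' over bins in `total_band` (endpoints inclusive on the discrete grid).
#'
#' @param spec A [power_spectrum()] covering `total_band`.
#' @param alpha_band,total_band Two-element Hz intervals; defaults 7-13 Hz
#'   within 1-55 Hz.
#'
#' @return A fraction in `[0, 1]`.
#' @export
relative_alpha_power <- function(spec, alpha_band = c(7, 13),
                                 total_band = c(1, 55)) {
  stopifnot(inherits(spec, "power_spectrum"))
  if (min(spec$freqs) > total_band[1] + 1e-8 ||
      max(spec$freqs) < total_band[2] - 1e-8) {
    stop_alphapaf("spectrum does not cover `total_band`", "alphapaf_config_error")
  }
  tot <- sum(spec$power[in_band(spec$freqs, total_band)])
  if (tot <= 0) {
    stop_alphapaf("total power in `total_band` is zero; relative power undefined",
                  "alphapaf_undefined_value")
  }
  sum(spec$power[in_band(spec$freqs, alpha_band)]) / tot
}
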