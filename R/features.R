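# The twenty click parameters: spectral peaks and notches, -3/-10 dB band
# edges and derived bandwidth/centre/Q, Teager-Kaiser duration, and the
# inter-click interval.  Spectra are estimated from 10 kHz high-passed,
# Hann-windowed snippets zero-padded to a 2048-point FFT (bin width
# ~244 Hz at 500 kHz).

.dsp_cache <- new.env(parent = emptyenv())

.cached_butter <- function(order, corner_hz, sample_rate) {
  key <- paste(order, corner_hz, sample_rate, sep = "_")
  if (is.null(.dsp_cache[[key]]))
    .dsp_cache[[key]] <- butter_highpass(order, corner_hz, sample_rate)
  .dsp_cache[[key]]
}

#' Estimate the magnitude spectrum of a click snippet
#'
#' The snippet is high-passed (10 kHz Butterworth by default), limited to a
#' 2.5 ms analysis window centred on the snippet, Hann-windowed,
#' zero-padded to `fft_length`, and transformed.  The magnitude is
#' normalised so the maximum is exactly 0 dB.
#'
#' @param snippet numeric waveform snippet.
#' @param sample_rate Hz.
#' @param fft_length FFT size (power of two recommended).
#' @param highpass_hz,highpass_order spectrum pre-filter (0 disables).
#' @return object of class `click_spectrum`: list with `freq_khz`
#'   (0..Nyquist), `db` (max = 0), `fft_length`, `window`.
#' @export
estimate_spectrum <- function(snippet, sample_rate = 500000,
                              fft_length = 2048, highpass_hz = 10000,
                              highpass_order = 4) {
  if (length(snippet) == 0 || all(snippet == 0))
    stop("cannot estimate a spectrum from an empty or all-zero snippet")
  x <- snippet
  if (highpass_hz > 0) {
    coefs <- .cached_butter(highpass_order, highpass_hz, sample_rate)
    x <- .iir_filter_cpp(coefs$b, coefs$a, x)
  }
  max_win <- min(round(0.0025 * sample_rate), fft_length)
  if (length(x) > max_win) {
    mid <- length(x) %/% 2
    lo <- mid - max_win %/% 2 + 1
    x <- x[lo:(lo + max_win - 1)]
  }
  x <- x * .hann(length(x))
  x <- c(x, numeric(fft_length - length(x)))
  mag <- Mod(fft(x))[1:(fft_length %/% 2 + 1)]
  peak <- max(mag)
  if (peak == 0) stop("degenerate snippet: zero spectrum")
  db <- 20 * log10(pmax(mag, peak * 1e-10) / peak)
  structure(list(freq_khz = (0:(fft_length %/% 2)) * sample_rate /
                   fft_length / 1000,
                 db = db, fft_length = fft_length, window = "hann"),
            class = "click_spectrum")
}

# indices of local maxima of v (leftmost sample of any plateau)
.local_maxima <- function(v) {
  n <- length(v)
  if (n < 3) return(integer())
  which(v[2:(n - 1)] > v[1:(n - 2)] & v[2:(n - 1)] >= v[3:n]) + 1L
}

#' Spectral peak and notch parameters
#'
#' `peak` is the global spectral maximum.  `peak2`/`peak3` are the highest
#' remaining local maxima outside a +/- `exclusion_khz` zone around
#' previously selected peaks (falling back to the highest remaining bins
#' when the spectrum has no further local maxima).  `trough` (`trough2`) is
#' the lowest-dB frequency strictly between `peak` and `peak2` (`peak2` and
#' `peak3`); the peak-to-peak values are absolute frequency differences.
#'
#' @param spectrum a [estimate_spectrum()] result.
#' @param exclusion_khz half-width of the exclusion zone around selected
#'   peaks, kHz.
#' @return named numeric vector: peak, peak2, peak3, trough, trough2,
#'   peakToPeak2, peakToPeak3, peak2ToPeak3 (all kHz).
#' @export
spectral_peaks <- function(spectrum, exclusion_khz = 2) {
  f <- spectrum$freq_khz
  db <- spectrum$db
  i_peak <- which.max(db)
  locmax <- .local_maxima(db)

  pick_next <- function(exclude_centres) {
    ok <- rep(TRUE, length(f))
    for (c0 in exclude_centres) ok <- ok & abs(f - f[c0]) > exclusion_khz
    cand <- intersect(locmax, which(ok))
    if (length(cand) == 0) cand <- which(ok)   # fallback: order statistics
    if (length(cand) == 0) return(NA_integer_)
    cand[which.max(db[cand])]
  }
  i_peak2 <- pick_next(i_peak)
  i_peak3 <- pick_next(c(i_peak, i_peak2))

  trough_between <- function(i, j) {
    if (is.na(i) || is.na(j)) return(NA_real_)
    lo <- min(i, j)
    hi <- max(i, j)
    if (hi - lo < 2) return(f[lo] + (f[hi] - f[lo]) / 2)
    inner <- (lo + 1):(hi - 1)
    f[inner[which.min(db[inner])]]
  }

  c(peak = f[i_peak],
    peak2 = f[i_peak2],
    peak3 = f[i_peak3],
    trough = trough_between(i_peak, i_peak2),
    trough2 = trough_between(i_peak2, i_peak3),
    peakToPeak2 = abs(f[i_peak] - f[i_peak2]),
    peakToPeak3 = abs(f[i_peak] - f[i_peak3]),
    peak2ToPeak3 = abs(f[i_peak2] - f[i_peak3]))
}

#' Band-edge metrics at a given dB drop
#'
#' `fmin`/`fmax` are the outermost frequencies at which the spectrum
#' crosses `-drop_db` relative to its maximum, linearly interpolated
#' between the straddling bins.  `BW = fmax - fmin`,
#' `center = fmin + BW / 2`, `Q = center / BW` (undefined when `BW` is 0).
#'
#' @param spectrum a [estimate_spectrum()] result.
#' @param drop_db 3 or 10.
#' @return named numeric vector: fmin, fmax, BW, center (kHz) and Q.
#' @export
band_metrics <- function(spectrum, drop_db = 3) {
  f <- spectrum$freq_khz
  db <- spectrum$db
  thr <- -abs(drop_db)
  above <- which(db >= thr)
  i1 <- min(above)
  i2 <- max(above)
  fmin <- if (i1 == 1) f[1] else {
    f[i1 - 1] + (thr - db[i1 - 1]) * (f[i1] - f[i1 - 1]) /
      (db[i1] - db[i1 - 1])
  }
  fmax <- if (i2 == length(f)) f[i2] else {
    f[i2] + (thr - db[i2]) * (f[i2 + 1] - f[i2]) / (db[i2 + 1] - db[i2])
  }
  bw <- fmax - fmin
  center <- fmin + bw / 2
  c(fmin = fmin, fmax = fmax, BW = bw, center = center,
    Q = if (bw > 0) center / bw else NA_real_)
}

#' Teager-Kaiser click duration
#'
#' Counts the samples whose Teager-Kaiser energy exceeds 100 times the 40th
#' percentile of the snippet's Teager-Kaiser energy, and converts the count
#' to microseconds.  Scale invariant by construction; an all-zero snippet
#' or a constant-envelope tone yields 0.
#'
#' @param snippet numeric waveform snippet (length >= 3).
#' @param sample_rate Hz.
#' @return duration in microseconds.
#' @export
click_duration <- function(snippet, sample_rate = 500000) {
  stopifnot(length(snippet) >= 3)
  psi <- .tk_energy_cpp(snippet)
  psi <- psi[2:(length(psi) - 1)]
  thr <- 100 * quantile(psi, 0.4, names = FALSE, type = 7)
  sum(psi > thr) / sample_rate * 1e6
}

#' Compute the twenty click parameters for one snippet
#'
#' Assembles the full click feature vector: the eight peak/notch
#' frequencies, -3 and -10 dB band metrics, Teager-Kaiser duration, and the
#' inter-click interval (time since the previous click in the train;
#' `NA` for the first click).
#'
#' @param snippet waveform snippet.
#' @param sample_rate Hz.
#' @param time_s detection time of this click, s.
#' @param prev_time_s detection time of the previous click in the train, or
#'   `NA`.
#' @param ... passed to [estimate_spectrum()].
#' @return named numeric vector of length 20 (see [feature_names()]).
#' @export
compute_click_features <- function(snippet, sample_rate = 500000,
                                   time_s = NA_real_,
                                   prev_time_s = NA_real_, ...) {
  spec <- estimate_spectrum(snippet, sample_rate, ...)
  pk <- spectral_peaks(spec)
  b3 <- band_metrics(spec, 3)
  b10 <- band_metrics(spec, 10)
  out <- c(pk[c("peak", "peak2", "peak3", "trough", "trough2",
                "peakToPeak2", "peakToPeak3", "peak2ToPeak3")],
           Q_10dB = unname(b10["Q"]), Q_3dB = unname(b3["Q"]),
           fmin_10dB = unname(b10["fmin"]), fmin_3dB = unname(b3["fmin"]),
           fmax_10dB = unname(b10["fmax"]), fmax_3dB = unname(b3["fmax"]),
           BW_10dB = unname(b10["BW"]), BW_3dB = unname(b3["BW"]),
           centerHz_10dB = unname(b10["center"]),
           centerHz_3dB = unname(b3["center"]),
           duration = click_duration(snippet, sample_rate),
           ici = time_s - prev_time_s)
  out[.feature_names]
}

#' Batch feature extraction for a detection set
#'
#' Computes the twenty parameters for every detection of one click train
#' (the ICI is the backward difference of detection times) and assigns each
#' click its detector code from the measured peak frequency.
#'
#' @param detections a [detect_clicks()] result.
#' @param ... passed to [estimate_spectrum()].
#' @return data.frame with `time_s`, `snr_db`, `detector_code`, and the 20
#'   feature columns.
#' @export
extract_click_features <- function(detections, ...) {
  det <- detections$detections
  n <- nrow(det)
  if (n == 0) {
    out <- as.data.frame(matrix(numeric(), 0, length(.feature_names),
                                dimnames = list(NULL, .feature_names)))
    return(cbind(data.frame(time_s = numeric(), snr_db = numeric(),
                            detector_code = integer()), out))
  }
  feats <- matrix(NA_real_, n, length(.feature_names),
                  dimnames = list(NULL, .feature_names))
  for (i in seq_len(n)) {
    prev <- if (i > 1) det$time_s[i - 1] else NA_real_
    feats[i, ] <- compute_click_features(detections$snippets[[i]],
                                         detections$sample_rate,
                                         det$time_s[i], prev, ...)
  }
  cbind(data.frame(time_s = det$time_s, snr_db = det$snr_db,
                   detector_code = assign_detector_code(feats[, "peak"])),
        as.data.frame(feats))
}
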