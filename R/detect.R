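# Click detector: 4 kHz Butterworth high-pass, Teager-Kaiser short-term
# energy smoothed over 0.1 ms, median noise floor, 14 dB SNR threshold.
# Detections closer than one snippet length are merged (largest peak kept).

#' Click detector configuration
#'
#' Defaults mirror a standard PAM click-detector setup: a 14 dB
#' signal-to-noise minimum threshold after a 4th-order IIR Butterworth
#' high-pass with a 4 kHz corner, and 800-sample snippets (1.6 ms at
#' 500 kHz) centred on the energy maximum.
#'
#' @param snr_threshold_db minimum detection SNR, dB.
#' @param highpass_order,highpass_hz high-pass filter order and corner.
#' @param snippet_samples extracted waveform snippet length; also the
#'   minimum separation between detections.
#' @param smooth_s energy smoothing window, s.
#' @return object of class `detector_config`.
#' @export
detector_config <- function(snr_threshold_db = 14, highpass_order = 4,
                            highpass_hz = 4000, snippet_samples = 800,
                            smooth_s = 1e-4) {
  stopifnot(snr_threshold_db > 0, snippet_samples > 2, smooth_s > 0)
  structure(list(snr_threshold_db = snr_threshold_db,
                 highpass_order = highpass_order,
                 highpass_hz = highpass_hz,
                 snippet_samples = snippet_samples,
                 smooth_s = smooth_s),
            class = "detector_config")
}

#' Detect echolocation clicks in a recording
#'
#' High-passes the samples, computes smoothed Teager-Kaiser energy, sets
#' the noise floor to the median smoothed energy, and reports one detection
#' per energy excursion exceeding the floor by at least the SNR threshold.
#' Each detection carries a waveform snippet centred on its energy maximum.
#'
#' @param samples numeric sample vector (one channel).
#' @param sample_rate sampling rate, Hz.
#' @param config a [detector_config()].
#' @param t0 absolute time of `samples[1]`, s; detection times are
#'   reported on this absolute axis.
#' @return object of class `click_detections`: a list with `detections`
#'   (data.frame `time_s`, `snr_db`), `snippets` (list of numeric
#'   vectors), `sample_rate`, `noise_floor`.
#' @export
detect_clicks <- function(samples, sample_rate = 500000,
                          config = detector_config(), t0 = 0) {
  if (length(samples) == 0) {
    return(structure(list(
      detections = data.frame(time_s = numeric(), snr_db = numeric()),
      snippets = list(), sample_rate = sample_rate, noise_floor = NA_real_),
      class = "click_detections"))
  }
  if (config$highpass_hz >= sample_rate / 2)
    stop("high-pass corner must be below Nyquist")
  filtered <- highpass(samples, config$highpass_order, config$highpass_hz,
                       sample_rate)
  smooth <- max(1L, round(config$smooth_s * sample_rate))
  energy <- .boxcar_cpp(.tk_energy_cpp(filtered), smooth)
  hits <- .tk_detect_cpp(energy, config$snr_threshold_db,
                         as.integer(config$snippet_samples))
  idx <- hits$index
  half <- config$snippet_samples %/% 2L
  n <- length(samples)
  snippets <- lapply(idx, function(i) {
    lo <- i - half
    hi <- lo + config$snippet_samples - 1L
    shift <- max(0L, 1L - lo) - max(0L, hi - n)
    lo <- lo + shift
    hi <- hi + shift
    filtered[max(1L, lo):min(n, hi)]
  })
  structure(list(
    detections = data.frame(time_s = t0 + (idx - 1) / sample_rate,
                            snr_db = hits$snr_db),
    snippets = snippets, sample_rate = sample_rate,
    noise_floor = hits$noise_floor),
    class = "click_detections")
}

#' @export
print.click_detections <- function(x, ...) {
  cat("click_detections:", nrow(x$detections), "detections\n")
  invisible(x)
}

#' Assign a detector frequency code to a peak frequency
#'
#' The detector bands are half-open kHz bins: 1 = \[4, 20), 2 = \[20, 50),
#' 3 = \[50, 70), 4 = \[70, 100), 5 = \[100, 150), 6 = \[150, 250); any
#' other positive frequency maps to 0 (unclassified).
#'
#' @param peak_khz vector of positive peak frequencies in kHz.
#' @return integer vector of detector codes in 0..6.
#' @export
assign_detector_code <- function(peak_khz) {
  if (any(!is.finite(peak_khz)) || any(peak_khz <= 0))
    stop("peak frequency must be positive and finite")
  lo <- c(4, 20, 50, 70, 100, 150)
  hi <- c(20, 50, 70, 100, 150, 250)
  code <- integer(length(peak_khz))
  for (k in seq_along(lo)) {
    code[peak_khz >= lo[k] & peak_khz < hi[k]] <- k
  }
  code
}
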