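# Filter design and small DSP helpers.  Only what the pipeline needs: a
# Butterworth high-pass designed by bilinear transform, applied with the
# C++ IIR kernel.

#' Design a digital Butterworth high-pass filter
#'
#' Poles of the analog Butterworth low-pass prototype are frequency
#' transformed to a high-pass with pre-warped corner `corner_hz` and mapped
#' to the z-plane by the bilinear transform.  The gain is normalised to
#' exactly 1 at the Nyquist frequency, so the magnitude response is
#' maximally flat in the passband and -3 dB at the corner.
#'
#' @param order filter order (number of poles).
#' @param corner_hz corner (-3 dB) frequency in Hz; must be below Nyquist.
#' @param sample_rate sampling rate in Hz.
#' @return list with numerator `b` and denominator `a` coefficients.
#' @export
butter_highpass <- function(order, corner_hz, sample_rate) {
  if (corner_hz <= 0 || corner_hz >= sample_rate / 2)
    stop("corner frequency must lie in (0, Nyquist)")
  if (order < 1) stop("order must be >= 1")
  w <- tan(pi * corner_hz / sample_rate)       # pre-warped analog corner
  k <- seq_len(order)
  p_lp <- exp(1i * pi * (2 * k + order - 1) / (2 * order))  # unit LP poles
  p_hp <- w / p_lp                             # LP -> HP: s -> w/s
  p_z <- (1 + p_hp) / (1 - p_hp)               # bilinear, T = 2
  a <- Re(.poly_from_roots(p_z))
  b <- Re(.poly_from_roots(rep(1 + 0i, order)))  # order zeros at z = 1 (DC)
  # unit gain at Nyquist (z = -1)
  zm <- (-1)^(0:order)
  b <- b * sum(a * zm) / sum(b * zm)
  list(b = b, a = a)
}

.poly_from_roots <- function(r) {
  coefs <- 1 + 0i
  for (root in r) coefs <- c(coefs, 0) - c(0, coefs * root)
  coefs
}

#' Apply a high-pass filter to a sample vector
#'
#' Convenience wrapper: designs (or reuses) a Butterworth high-pass and runs
#' it across the samples in one forward pass.
#'
#' @param samples numeric vector of audio samples.
#' @param order,corner_hz,sample_rate see [butter_highpass()].
#' @param coefs optional precomputed `list(b, a)`; overrides the design
#'   arguments.
#' @return filtered samples.
#' @export
highpass <- function(samples, order = 4, corner_hz = 4000,
                     sample_rate = 500000, coefs = NULL) {
  if (is.null(coefs)) coefs <- butter_highpass(order, corner_hz, sample_rate)
  .iir_filter_cpp(coefs$b, coefs$a, samples)
}

# Hann window of length n (periodic-symmetric form used for spectra)
.hann <- function(n) {
  if (n == 1) return(1)
  0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
}

#' Teager-Kaiser energy of a sample vector
#'
#' \eqn{\psi[n] = x[n]^2 - x[n-1] x[n+1]}; the first and last samples are 0.
#'
#' @param samples numeric vector.
#' @return numeric vector of the same length.
#' @export
tk_energy <- function(samples) .tk_energy_cpp(samples)
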