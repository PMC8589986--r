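# The twenty click parameters: spectra, peaks/notches, band edges,
# Teager-Kaiser duration, assembled feature vectors.

test_that("spectrum estimation finds component frequencies", {
  wf <- synthesize_click(
    data.frame(freq_khz = 60, amp_db = 0, sigma_us = 50), 5e5)
  spec <- estimate_spectrum(wf$samples, 5e5)
  bin <- 5e5 / 2048 / 1000
  expect_lt(abs(spec$freq_khz[which.max(spec$db)] - 60), bin + 1e-9)
  expect_equal(max(spec$db), 0)

  # two-component click: both centres are local maxima of the dB spectrum
  comp <- data.frame(freq_khz = c(43.7, 49.3), amp_db = c(0, -1),
                     sigma_us = c(80, 80), sign = c(1, -1))
  wf2 <- synthesize_click(comp, 5e5)
  spec2 <- estimate_spectrum(wf2$samples, 5e5)
  # the Hann window broadens the lobes slightly: allow two bins
  locmax <- echoclass:::.local_maxima(spec2$db)
  locs <- spec2$freq_khz[locmax]
  expect_true(any(abs(locs - 43.7) <= 2 * bin))
  expect_true(any(abs(locs - 49.3) <= 2 * bin))

  expect_error(estimate_spectrum(numeric(100)), "all-zero")
})

test_that("spectral peak selection matches the exhaustive toy oracle", {
  # toy spectrum: bins 40..60 kHz, values {-6,-20,0,-15,-3} dB; exhaustive
  # search over the 5 bins gives peak=50, peak2=60, trough=55
  toy <- structure(list(freq_khz = c(40, 45, 50, 55, 60),
                        db = c(-6, -20, 0, -15, -3)),
                   class = "click_spectrum")
  pk <- spectral_peaks(toy)
  expect_equal(unname(pk["peak"]), 50)
  expect_equal(unname(pk["peak2"]), 60)
  expect_equal(unname(pk["trough"]), 55)
  expect_equal(unname(pk["peakToPeak2"]), 10)
  expect_equal(unname(pk["peak3"]), 40)
  expect_equal(unname(pk["trough2"]), 45)
  # peak-to-peak differences are plain subtractions
  expect_equal(unname(pk["peakToPeak3"]), 10)
  expect_equal(unname(pk["peak2ToPeak3"]), 20)
})

test_that("strictly unimodal spectra fall back to order statistics", {
  f <- seq(0, 100, by = 0.5)
  db <- -((f - 50)^2) / 50          # smooth parabola, single maximum
  uni <- structure(list(freq_khz = f, db = db), class = "click_spectrum")
  pk <- spectral_peaks(uni)
  expect_equal(unname(pk["peak"]), 50)
  # fallback: second highest bin outside the 2 kHz exclusion zone
  expect_equal(abs(unname(pk["peakToPeak2"])), 2.5)
  expect_true(unname(pk["trough"]) > min(pk["peak"], pk["peak2"]) &&
                unname(pk["trough"]) < max(pk["peak"], pk["peak2"]))
})

test_that("band metrics interpolate the outermost crossings", {
  # triangular spectrum with exact -3 dB crossings at 55 and 65
  f <- seq(40, 80, by = 1)
  db <- -abs(f - 60) * 0.6
  tri <- structure(list(freq_khz = f, db = db), class = "click_spectrum")
  b3 <- band_metrics(tri, 3)
  expect_equal(unname(b3["fmin"]), 55)
  expect_equal(unname(b3["fmax"]), 65)
  expect_equal(unname(b3["BW"]), 10)
  expect_equal(unname(b3["center"]), 60)
  expect_equal(unname(b3["Q"]), 6)
  b10 <- band_metrics(tri, 10)
  expect_gte(unname(b10["BW"]), unname(b3["BW"]))
})

test_that("gabor band edges match the closed-form spectrum within a bin", {
  bin <- 5e5 / 2048 / 1000
  for (sig_us in c(35, 50, 80)) {
    wf <- synthesize_click(
      data.frame(freq_khz = 60, amp_db = 0, sigma_us = sig_us), 5e5)
    x <- numeric(800)
    x[400 - wf$center_index + seq_along(wf$samples)] <- wf$samples
    spec <- estimate_spectrum(x, 5e5)
    for (drop in c(3, 10)) {
      half_khz <- gabor_halfwidth_hz(sig_us * 1e-6, drop) / 1000
      b <- band_metrics(spec, drop)
      expect_lt(abs(unname(b["fmin"]) - (60 - half_khz)), bin)
      expect_lt(abs(unname(b["fmax"]) - (60 + half_khz)), bin)
    }
  }
})

test_that("teager-kaiser duration handles the degenerate cases", {
  expect_equal(click_duration(numeric(100), 5e5), 0)
  tone <- sin(2 * pi * 0.1 * (0:799))
  expect_equal(click_duration(tone, 5e5), 0)
  # noise-free gabor in a mostly-silent window: duration equals the count
  # of samples whose psi (computed directly) exceeds 100x its 40th pctile
  wf <- synthesize_click(
    data.frame(freq_khz = 60, amp_db = 0, sigma_us = 40), 5e5)
  x <- numeric(800)
  x[400 - wf$center_index + seq_along(wf$samples)] <- wf$samples
  psi <- x^2 - c(0, head(x, -1)) * c(x[-1], 0)
  psi <- psi[2:799]
  expected <- sum(psi > 100 * quantile(psi, 0.4, names = FALSE)) / 5e5 * 1e6
  expect_equal(click_duration(x, 5e5), expected)
  expect_gt(expected, 0)
})

test_that("all twenty parameters are scale invariant", {
  set.seed(77)
  wf <- synthesize_click(species_template("narwhal")$components, 5e5)
  x <- numeric(800)
  x[400 - wf$center_index + seq_along(wf$samples)] <- wf$samples
  x <- x + rnorm(800, 0, 0.01)
  base <- compute_click_features(x, 5e5, time_s = 1, prev_time_s = 0.9)
  for (k in c(0.001, 7, 3000)) {
    expect_equal(compute_click_features(k * x, 5e5, 1, 0.9), base,
                 tolerance = 1e-10)
  }
})

test_that("band-edge ordering holds across random clicks", {
  set.seed(12)
  tpls <- default_templates()
  for (i in 1:20) {
    tpl <- tpls[[1 + i %% 2]]
    comp <- echoclass:::.shift_components(tpl$components, rnorm(1, 0, 8))
    wf <- synthesize_click(comp, 5e5)
    x <- numeric(800)
    x[400 - wf$center_index + seq_along(wf$samples)] <- wf$samples
    x <- x + rnorm(800, 0, 10^(-runif(1, 1, 2)))
    v <- compute_click_features(x, 5e5)
    expect_lte(v["fmin_10dB"], v["fmin_3dB"])
    expect_lte(v["fmin_3dB"], v["peak"])
    expect_lte(v["peak"], v["fmax_3dB"])
    expect_lte(v["fmax_3dB"], v["fmax_10dB"])
    expect_equal(unname(v["BW_3dB"]),
                 unname(v["fmax_3dB"] - v["fmin_3dB"]))
    expect_equal(unname(v["centerHz_3dB"]),
                 unname(v["fmin_3dB"] + v["BW_3dB"] / 2))
    expect_true(v["trough"] >= min(v["peak"], v["peak2"]) &
                  v["trough"] <= max(v["peak"], v["peak2"]))
  }
})

test_that("feature vectors carry the inter-click interval", {
  wf <- synthesize_click(species_template("beluga")$components, 5e5)
  x <- numeric(800)
  x[400 - wf$center_index + seq_along(wf$samples)] <- wf$samples
  v <- compute_click_features(x, 5e5, time_s = 2.1, prev_time_s = 2.0)
  expect_equal(unname(v["ici"]), 0.1, tolerance = 1e-12)
  expect_equal(length(v), 20)
  expect_named(v, feature_names())
  v1 <- compute_click_features(x, 5e5, time_s = 2.1)
  expect_true(is.na(v1["ici"]))
})
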