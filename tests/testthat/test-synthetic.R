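# Click synthesis, species templates, dataset generation, rendering.

test_that("synthesized click spectrum peaks at the dominant component", {
  wf <- synthesize_click(
    data.frame(freq_khz = 68.7, amp_db = 0, sigma_us = 50), 5e5)
  # discrete-spectrum oracle on the rendered waveform
  nfft <- 8192
  mag <- Mod(fft(c(wf$samples, numeric(nfft - length(wf$samples)))))
  mag <- mag[1:(nfft / 2 + 1)]
  f_argmax <- (which.max(mag) - 1) * 5e5 / nfft / 1000
  expect_lt(abs(f_argmax - 68.7), 5e5 / nfft / 1000 + 1e-9)  # within 1 bin
})

test_that("empty component list yields an all-zero snippet", {
  wf <- synthesize_click(data.frame(freq_khz = numeric(),
                                    amp_db = numeric(),
                                    sigma_us = numeric()), 5e5)
  expect_true(all(wf$samples == 0))
})

test_that("two equal-amplitude anti-phase components leave a local minimum between them", {
  comp <- data.frame(freq_khz = c(43.7, 49.3), amp_db = c(0, 0),
                     sigma_us = c(80, 80), sign = c(1, -1))
  expect_error(synthesize_click(comp), "exactly one component")
  # spec-level check with one at 0 dB and epsilon below for the second
  comp$amp_db <- c(0, -1e-9)
  wf <- synthesize_click(comp, 5e5)
  nfft <- 2^15
  mag <- Mod(fft(c(wf$samples, numeric(nfft - length(wf$samples)))))
  fr <- (0:(nfft / 2)) * 5e5 / nfft / 1000
  mag <- mag[seq_along(fr)]
  between <- fr > 43.7 & fr < 49.3
  expect_lt(min(mag[between]), 0.5 * min(mag[which(between)[1] - 1],
                                         mag[max(which(between)) + 1]))
})

test_that("component frequencies at or above Nyquist are rejected", {
  expect_error(synthesize_click(
    data.frame(freq_khz = 260, amp_db = 0, sigma_us = 50), 5e5), "Nyquist")
})

test_that("sample_event_clicks is deterministic and respects n_clicks", {
  tpl <- species_template("narwhal")
  set.seed(10)
  a <- sample_event_clicks(tpl, 20, render = FALSE)
  set.seed(10)
  b <- sample_event_clicks(tpl, 20, render = FALSE)
  expect_identical(a, b)
  expect_true(all(diff(a$time_s) > 0))

  one <- sample_event_clicks(tpl, 1, render = FALSE)
  expect_equal(nrow(one), 1)
})

test_that("realized inter-click intervals have the template mode", {
  tpl <- species_template("narwhal", ici_event_cv = 0)
  set.seed(3)
  cl <- sample_event_clicks(tpl, 500, render = FALSE,
                            event_offset_khz = 0)
  est <- ici_mode(cl$time_s)
  expect_lt(abs(est - 0.1435) / 0.1435, 0.10)
})

test_that("species templates encode the documented spectral contrast", {
  tpls <- default_templates()
  # narwhal: >= 2 components with a deep notch; beluga: smooth single lobe
  expect_gte(nrow(tpls$narwhal$components), 2)
  expect_gte(tpls$narwhal$notch_depth_db, 6)
  expect_lt(tpls$beluga$notch_depth_db, 1)
  for (tpl in tpls) {
    expect_equal(sum(tpl$components$amp_db == 0), 1)
    expect_true(all(tpl$components$amp_db <= 0))
    expect_true(all(tpl$components$freq_khz > 0))
    expect_gt(tpl$ici_mode_s, 0)
  }
  # calibration: the pipeline's own estimator sees the reference values
  mb <- echoclass:::.measured_metrics(tpls$beluga$components)
  expect_equal(mb$peak, 68.7, tolerance = 0.01)   # relative: within a bin
  expect_equal(mb$fmin, 65.0, tolerance = 0.005)
  expect_equal(mb$fmax, 74.2, tolerance = 0.005)
  mn <- echoclass:::.measured_metrics(tpls$narwhal$components)
  expect_equal(mn$peak, 43.7, tolerance = 0.01)
  expect_equal(mn$fmin, 40.5, tolerance = 0.005)
})

test_that("generate_dataset reproduces the event/encounter design", {
  ds <- generate_dataset(sim_config(seed = 5,
                                    clicks_per_event_median = 8,
                                    clicks_per_event_sdlog = 0.1))
  expect_equal(nrow(ds$events), 81)
  expect_equal(sum(ds$events$species == "beluga"), 19)
  expect_equal(sum(ds$events$species == "narwhal"), 62)
  enc <- unique(ds$events[, c("species", "encounter")])
  expect_equal(sum(enc$species == "beluga"), 2)
  expect_equal(sum(enc$species == "narwhal"), 5)
  # every click inside exactly one event window
  m <- merge(ds$clicks, ds$events[, c("event_id", "win_start", "win_end")])
  expect_true(all(m$time_s >= m$win_start & m$time_s < m$win_end))

  ds2 <- generate_dataset(sim_config(seed = 5,
                                     clicks_per_event_median = 8,
                                     clicks_per_event_sdlog = 0.1))
  expect_identical(ds$clicks, ds2$clicks)
})

test_that("rendered segments have the configured block size and noise", {
  cfg <- sim_config(n_events = c(beluga = 1, narwhal = 1),
                    n_encounters = c(beluga = 1, narwhal = 1),
                    clicks_per_event_median = 5,
                    clicks_per_event_sdlog = 0.01,
                    window_s = c(beluga = 6, narwhal = 6), seed = 2)
  # fixed per-event ICI so the short train stays inside segment 1
  tpls <- list(beluga = species_template("beluga", ici_event_cv = 0),
               narwhal = species_template("narwhal", ici_event_cv = 0))
  ds <- generate_dataset(cfg, tpls)
  rec <- render_recording(ds, "beluga_1", segments = 1)
  expect_equal(length(rec$blocks[[1]]), 5 * 5e5)  # 2.5e6 samples per block

  # pure noise block: RMS recovers noise_sd within 1%
  expect_lt(max(ds$clicks$time_s[ds$clicks$encounter == "beluga_1"]), 4.9)
  noise <- render_recording(ds, "beluga_1", segments = 2, noise_sd = 0.7)
  blk <- noise$blocks[[1]]
  expect_equal(sqrt(mean(blk^2)), 0.7, tolerance = 0.01)

  # noiseless render: silence outside click supports
  clean <- render_recording(ds, "beluga_1", segments = 1, noise_sd = 0)
  blk <- clean$blocks[[1]]
  expect_gt(sum(blk == 0), 0.8 * length(blk))
  expect_gt(max(abs(blk)), 0)
})

test_that("configs that cannot hold a click train are rejected", {
  expect_error(
    generate_dataset(sim_config(window_s = c(beluga = 0.2, narwhal = 120))),
    "window")
  expect_error(sim_config(noise_sd = -1))
})
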