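# Shared fixtures.  Everything is generated in code; the expensive
# full-scale pipeline runs used by the acceptance criteria are computed
# once per session and memoised here.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# a single-component Gabor click embedded in noise at a given detector SNR
make_noisy_click <- function(freq_khz = 68.7, sigma_us = 50, snr_db = 30,
                             sample_rate = 5e5, dur_s = 0.2,
                             at_s = dur_s / 2, noise_sd = 1, seed = 1) {
  set.seed(seed)
  x <- rnorm(round(dur_s * sample_rate), 0, noise_sd)
  wf <- synthesize_click(
    data.frame(freq_khz = freq_khz, amp_db = 0, sigma_us = sigma_us),
    sample_rate)
  smooth <- round(1e-4 * sample_rate)
  upk <- max(.boxcar(tk_energy(wf$samples), smooth))
  gain <- noise_sd * sqrt(10^(snr_db / 10) / upk)
  pos <- round(at_s * sample_rate)
  idx <- pos + seq_along(wf$samples) - wf$center_index
  x[idx] <- x[idx] + gain * wf$samples
  list(samples = x, sample_rate = sample_rate, time_s = pos / sample_rate)
}

# plain-R boxcar used by fixtures (independent of the C++ kernel)
.boxcar <- function(x, width) {
  h <- width %/% 2
  n <- length(x)
  vapply(seq_len(n), function(i) {
    mean(x[max(1, i - h):min(n, i + h)])
  }, numeric(1))
}

# well-separated two-class Gaussian feature table for forest unit tests
make_separable_table <- function(n_a = 19, n_b = 62, p = 20, gap = 6,
                                 seed = 42) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n_a * p), n_a, p),
             matrix(rnorm(n_b * p, mean = c(rep(gap, 3), rep(0, p - 3))),
                    n_b, p, byrow = TRUE))
  colnames(x) <- paste0("v", seq_len(p))
  list(x = x, y = factor(rep(c("a", "b"), c(n_a, n_b))))
}

# Synthetic click FEATURE table (no audio): feature distributions mimic the
# two species' click statistics closely enough to exercise the two-stage
# classifier logic quickly.  Used by banter/encounter unit tests; the
# real waveform pipeline is exercised in the acceptance tests.
make_click_table <- function(n_enc = c(beluga = 2, narwhal = 5),
                             events_per_enc = 5, clicks_per_event = 60,
                             seed = 7) {
  set.seed(seed)
  rows <- list()
  for (sp in names(n_enc)) {
    mu <- if (sp == "beluga") 68.7 else 43.7
    for (enc in seq_len(n_enc[[sp]])) {
      for (ev in seq_len(events_per_enc)) {
        ev_off <- rnorm(1, 0, if (sp == "beluga") 10.1 else 7.8)
        n <- clicks_per_event
        peak <- mu + ev_off + rnorm(n, 0, 2)
        # sprinkle variants so detectors 2..5 are populated for both
        shift <- sample(c(0, 40, -30), n, TRUE, prob = c(0.8, 0.1, 0.1))
        peak <- pmax(peak + shift, 21)
        times <- cumsum(runif(n, 0.05, 0.25))
        feats <- data.frame(
          peak = peak, peak2 = peak + rnorm(n, 5.6, 1),
          peak3 = peak + rnorm(n, 11, 2),
          trough = peak + rnorm(n, 4.4, 1),
          trough2 = peak + rnorm(n, 8, 1.5),
          peakToPeak2 = abs(rnorm(n, 5.6, 1)),
          peakToPeak3 = abs(rnorm(n, 11, 2)),
          peak2ToPeak3 = abs(rnorm(n, 5.5, 1)),
          Q_10dB = abs(rnorm(n, 4, 1)), Q_3dB = abs(rnorm(n, 15, 4)),
          fmin_10dB = peak - 7, fmin_3dB = peak - 3.5,
          fmax_10dB = peak + 9, fmax_3dB = peak + 4,
          BW_10dB = abs(rnorm(n, 16, 3)), BW_3dB = abs(rnorm(n, 7.5, 2)),
          centerHz_10dB = peak + 1, centerHz_3dB = peak + 0.2,
          duration = abs(rnorm(n, 300, 80)),
          ici = c(NA, diff(times)))
        if (sp == "beluga") {
          feats$peakToPeak2 <- abs(rnorm(n, 8, 3))  # no stereotyped notch
          feats$trough <- peak + rnorm(n, 6, 3)
        }
        rows[[length(rows) + 1]] <- cbind(
          data.frame(event_id = sprintf("%s_%d_e%02d", sp, enc, ev),
                     species = sp,
                     encounter = sprintf("%s_%d", sp, enc),
                     time_s = times,
                     detector_code = assign_detector_code(peak)),
          feats)
      }
    }
  }
  do.call(rbind, rows)
}

# small but full-scale-per-event simulated pipeline (few events) for
# integration tests
small_pipeline <- function() {
  memo("small_pipeline", {
    cfg <- sim_config(n_events = c(beluga = 3, narwhal = 4),
                      n_encounters = c(beluga = 1, narwhal = 2),
                      clicks_per_event_median = 20,
                      clicks_per_event_sdlog = 0.2,
                      window_s = c(beluga = 30, narwhal = 30),
                      seed = 99)
    ds <- generate_dataset(cfg)
    cl <- pipeline_click_features(ds)
    list(dataset = ds, clicks = cl,
         events = suppressMessages(build_event_table(cl)))
  })
}

# Full default-scale pipeline runs for the acceptance criteria: seeds are
# fixed a priori; the first 5 serve the parameter-recovery criterion and
# all 10 the classifier-floor criterion.
acceptance_seeds <- 101:110

acceptance_run <- function(seed) {
  memo(paste0("acc_", seed), {
    ds <- generate_dataset(sim_config(seed = seed))
    cl <- pipeline_click_features(ds)
    ev <- suppressMessages(build_event_table(cl))
    rf <- fit_balanced_forest(ev[, feature_names()], ev$species,
                              ntree = 10000)
    set.seed(seed)
    perm_y <- sample(ev$species)
    rf_null <- fit_balanced_forest(ev[, feature_names()], perm_y,
                                   ntree = 2000, keep_forest = FALSE)
    bt <- fit_banter(cl, ntree1 = 20000, ntree2 = 20000)
    overall <- function(s) s$rate_pct[s$class == "Overall"]
    list(event_table = ev, clicks = cl,
         rf_overall = overall(rf$summary),
         rf_null_overall = overall(rf_null$summary),
         banter_overall = overall(bt$event_stage$summary),
         detectors = bt$call_stage$detectors)
  })
}
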