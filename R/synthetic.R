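# Synthetic click-train generator.
#
# Clicks are sums of Gaussian-enveloped cosines ("Gabor" components), so a
# single component has an exactly Gaussian magnitude spectrum and the -d dB
# half-width has the closed form sqrt(d * ln 10 / 40) / (pi * sigma_t).
# Component amplitudes are specified on the SPECTRAL dB scale (magnitude at
# the component's centre frequency relative to the 0 dB component); the
# time-domain gain compensates for the envelope width since a Gaussian
# envelope's spectral amplitude scales with sigma_t.  Components carry a
# sign: anti-phase components subtract in the spectrum and carve the deep
# interference notches characteristic of narwhal clicks, while same-phase
# components merge into the smooth, shouldered spectra seen for belugas.

#' Closed-form -d dB half-width of a single Gabor component
#'
#' For a Gaussian envelope with standard deviation `sigma_s` (seconds), the
#' magnitude spectrum is Gaussian and falls `drop_db` below its peak at
#' `sqrt(drop_db * log(10) / 40) / (pi * sigma_s)` Hz from the centre.
#'
#' @param sigma_s envelope standard deviation in seconds.
#' @param drop_db level drop in dB (3 or 10 for the band-edge parameters).
#' @return half-width in Hz.
#' @export
gabor_halfwidth_hz <- function(sigma_s, drop_db = 3) {
  sqrt(drop_db * log(10) / 40) / (pi * sigma_s)
}

# analytic magnitude spectrum of a component set at frequencies f_khz,
# optionally shifted by offset_khz; returns linear magnitude (0 dB == 1)
.components_spectrum <- function(components, f_khz, offset_khz = 0) {
  mag <- numeric(length(f_khz))
  for (i in seq_len(nrow(components))) {
    sig <- components$sigma_us[i] * 1e-6
    fc <- components$freq_khz[i] + offset_khz
    a <- 10^(components$amp_db[i] / 20) * components$sign[i]
    mag <- mag + a * exp(-2 * pi^2 * sig^2 * ((f_khz - fc) * 1000)^2)
  }
  abs(mag)
}

# peak, fmin and fmax at -drop dB of the analytic spectrum on a fine grid
.analytic_metrics <- function(components, drop_db = 3, grid_khz = 0.005) {
  f <- seq(5, 250, by = grid_khz)
  mag <- .components_spectrum(components, f)
  db <- 20 * log10(mag / max(mag))
  above <- which(db >= -drop_db)
  list(peak = f[which.max(db)], fmin = f[min(above)], fmax = f[max(above)])
}

.validate_components <- function(components) {
  stopifnot(is.data.frame(components))
  need <- c("freq_khz", "amp_db", "sigma_us")
  if (!all(need %in% names(components)))
    stop("components need columns freq_khz, amp_db, sigma_us")
  if (is.null(components$sign))
    components$sign <- rep(1, nrow(components))
  if (nrow(components)) {
    if (any(components$freq_khz <= 0)) stop("component frequencies must be > 0")
    if (any(components$amp_db > 0)) stop("component amplitudes must be <= 0 dB")
    if (sum(components$amp_db == 0) != 1)
      stop("exactly one component must sit at 0 dB")
    if (any(components$sigma_us <= 0)) stop("envelope sd must be > 0")
    if (!all(components$sign %in% c(-1, 1))) stop("sign must be -1 or 1")
  }
  components
}

# Calibrate the free template constants so the analytic spectrum reproduces
# the target event-mean peak and -3 dB edges.  Plain fixed-point iteration:
# the main-lobe centre tracks the peak, the main-lobe width tracks the
# lower edge, and (for the beluga shoulder) the shoulder amplitude tracks
# the upper edge.
.calibrate_components <- function(components, target_peak, target_fmin,
                                  target_fmax = NULL, shoulder_row = NULL) {
  for (iter in 1:40) {
    m <- .analytic_metrics(components)
    components$freq_khz <- components$freq_khz + (target_peak - m$peak)
    width_now <- m$peak - m$fmin
    width_want <- target_peak - target_fmin
    components$sigma_us[1] <- components$sigma_us[1] * width_now / width_want
    if (!is.null(target_fmax) && !is.null(shoulder_row)) {
      components$amp_db[shoulder_row] <-
        components$amp_db[shoulder_row] +
        1.5 * (target_fmax - m$fmax)
    }
    conv <- abs(target_peak - m$peak) < 1e-3 &&
      abs(target_fmin - m$fmin) < 1e-3 &&
      (is.null(target_fmax) || abs(target_fmax - m$fmax) < 1e-3)
    if (conv) break
  }
  components
}

# Metrics as the pipeline's own estimator sees them: render the click
# noise-free, centre it in a detector-length snippet, and measure with
# estimate_spectrum()/band_metrics().  Used for a final calibration polish
# so windowing/zero-padding bias does not shift the recovered event-mean
# calibration targets.
.measured_metrics <- function(components, sample_rate = 500000,
                              snippet = 800) {
  wf <- synthesize_click(components, sample_rate)
  x <- numeric(max(snippet, length(wf$samples)))
  mid <- length(x) %/% 2
  at <- mid - wf$center_index + 1L
  x[at:(at + length(wf$samples) - 1L)] <- wf$samples
  spec <- estimate_spectrum(x, sample_rate)
  b3 <- band_metrics(spec, 3)
  list(peak = spec$freq_khz[which.max(spec$db)],
       fmin = unname(b3["fmin"]), fmax = unname(b3["fmax"]))
}

# polish the analytic calibration against the measured estimator (damped
# fixed point; the peak is quantised to the FFT bin width so it uses a
# dead band of half a bin)
.polish_components <- function(components, target_peak, target_fmin,
                               target_fmax = NULL, shoulder_row = NULL) {
  bin <- 500000 / 2048 / 1000
  for (iter in 1:25) {
    m <- .measured_metrics(components)
    dp <- target_peak - m$peak
    if (abs(dp) <= bin / 2) dp <- 0
    components$freq_khz <- components$freq_khz + 0.7 * dp
    width_now <- max(m$peak - m$fmin, 0.3)
    components$sigma_us[1] <- components$sigma_us[1] *
      (1 + 0.7 * (width_now / (target_peak - target_fmin) - 1))
    if (!is.null(target_fmax) && !is.null(shoulder_row)) {
      components$amp_db[shoulder_row] <-
        components$amp_db[shoulder_row] + 1.0 * (target_fmax - m$fmax)
    }
    conv <- dp == 0 && abs(target_fmin - m$fmin) < 0.1 &&
      (is.null(target_fmax) || abs(target_fmax - m$fmax) < 0.1)
    if (conv) break
  }
  components
}

# deepest dip (dB below the lower of the flanking local maxima) in the
# analytic spectrum between the outermost component centres
.notch_depth <- function(components) {
  if (nrow(components) < 2) return(0)
  f <- seq(min(components$freq_khz) - 2, max(components$freq_khz) + 2,
           by = 0.01)
  db <- 20 * log10(pmax(.components_spectrum(components, f), 1e-12))
  db <- db - max(db)
  n <- length(db)
  locmax <- which(db[2:(n - 1)] > db[1:(n - 2)] &
                    db[2:(n - 1)] >= db[3:n]) + 1
  if (length(locmax) < 2) return(0)
  depth <- 0
  for (i in seq_len(length(locmax) - 1)) {
    seg <- db[locmax[i]:locmax[i + 1]]
    depth <- max(depth, min(db[locmax[i]], db[locmax[i + 1]]) - min(seg))
  }
  depth
}

#' Species click template
#'
#' Builds the spectral/temporal click model for one species, calibrated so
#' that the population of simulated acoustic events reproduces the
#' event-level summary statistics observed for wild animals: beluga events
#' centred on a 68.7 kHz peak with a smooth single-lobed spectrum
#' (-3 dB edges 65.0 / 74.2 kHz, the upper edge produced by a same-phase
#' high-frequency shoulder), narwhal events centred on 43.7 kHz with
#' anti-phase components producing spectral notches (peak2 near 49.3 kHz,
#' notch near 48 kHz).  Event-to-event variation in peak frequency uses the
#' observed standard deviation of event means (10.1 / 7.8 kHz);
#' click-to-click variation within an event is 20% of that.  A small
#' fraction of "variant" (off-axis-like) clicks is shifted far in frequency
#' so that all four mid detector bands (20-150 kHz) are populated for both
#' species, as in the field data; the base template is offset so variants
#' leave the population mean peak unchanged.
#'
#' @param species `"beluga"` or `"narwhal"`.
#' @param between_event_jitter_sd sd (kHz) of the event-level frequency
#'   offset (default: the observed sd of event-mean peak frequency).
#' @param within_event_jitter_sd sd (kHz) of click-level offsets within an
#'   event (default 20% of `between_event_jitter_sd`).
#' @param ici_mode_s species mean of the event inter-click-interval mode, s.
#' @param ici_event_cv coefficient of variation of the event-level ICI mode
#'   (log-normal across events; 0 disables between-event ICI variation).
#' @param ici_dispersion log-scale sd of click intervals within an event.
#' @param snr_range detection signal-to-noise range (dB) sampled uniformly
#'   per click.
#' @param window_s event time-window length for this species (s).
#' @return an object of class `species_template`.
#' @export
species_template <- function(species = c("beluga", "narwhal"),
                             between_event_jitter_sd = NULL,
                             within_event_jitter_sd = NULL,
                             ici_mode_s = NULL,
                             ici_event_cv = NULL,
                             ici_dispersion = 0.15,
                             snr_range = c(20, 40),
                             window_s = NULL) {
  species <- match.arg(species)
  if (species == "beluga") {
    comp <- data.frame(
      freq_khz = c(68.7, 77.0),
      amp_db = c(0, -8),
      sigma_us = c(35.8, 25.0),
      sign = c(1, 1))
    comp <- .calibrate_components(comp, target_peak = 68.7,
                                  target_fmin = 65.0, target_fmax = 74.2,
                                  shoulder_row = 2)
    comp <- .polish_components(comp, 68.7, 65.0, 74.2, shoulder_row = 2)
    defaults <- list(between = 10.1, ici_mode = 0.1779, ici_cv = 174.6 / 177.9,
                     window = 60,
                     variant = list(p_up = 0.08, up = c(40, 75),
                                    p_dn = 0.12, dn = c(15, 40)))
  } else {
    comp <- data.frame(
      freq_khz = c(43.7, 49.3, 55.4),
      amp_db = c(0, -4.5, -7),
      sigma_us = c(41.3, 80.0, 70.0),
      sign = c(1, -1, 1))
    comp <- .calibrate_components(comp, target_peak = 43.7,
                                  target_fmin = 40.5)
    comp <- .polish_components(comp, 43.7, 40.5)
    defaults <- list(between = 7.8, ici_mode = 0.1435, ici_cv = 70.1 / 143.5,
                     window = 120,
                     variant = list(p_up = 0.05, up = c(25, 85),
                                    p_dn = 0, dn = c(0, 0)))
  }
  between <- between_event_jitter_sd %||% defaults$between
  within <- within_event_jitter_sd %||% (0.2 * between)
  v <- defaults$variant
  # mean frequency shift contributed by variant clicks; the base template is
  # offset by its negative so the population mean peak stays on target
  variant_mean_shift <- v$p_up * mean(v$up) - v$p_dn * mean(v$dn)
  tpl <- structure(list(
    species = species,
    components = .validate_components(comp),
    between_event_jitter_sd = between,
    within_event_jitter_sd = within,
    notch_depth_db = .notch_depth(comp),
    ici_mode_s = ici_mode_s %||% defaults$ici_mode,
    ici_event_cv = ici_event_cv %||% defaults$ici_cv,
    ici_dispersion = ici_dispersion,
    snr_range = snr_range,
    variant = v,
    base_offset_khz = -variant_mean_shift,
    window_s = window_s %||% defaults$window),
    class = "species_template")
  stopifnot(tpl$ici_mode_s > 0)
  tpl
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default beluga + narwhal template pair
#' @return named list of two [species_template()] objects.
#' @export
default_templates <- function() {
  list(beluga = species_template("beluga"),
       narwhal = species_template("narwhal"))
}

#' Synthesize one click waveform
#'
#' Renders a sum of Gaussian-enveloped cosines centred in the returned
#' snippet.  Anti-phase components (`sign = -1`) are rendered with a pi
#' phase offset.  The waveform is normalised to unit peak absolute
#' amplitude.
#'
#' @param components data.frame with columns `freq_khz`, `amp_db` (spectral
#'   dB relative to the 0 dB component), `sigma_us`, and optional `sign`.
#'   An empty data.frame yields an all-zero snippet.
#' @param sample_rate sampling rate, Hz.  Component frequencies must lie
#'   below Nyquist.
#' @param support_sigmas rendered support, in units of the widest envelope
#'   sd, on each side of the centre.
#' @return list with `samples`, `sample_rate`, `center_index`.
#' @export
synthesize_click <- function(components, sample_rate = 500000,
                             support_sigmas = 5) {
  components <- .validate_components(components)
  if (nrow(components) == 0) {
    return(list(samples = numeric(65), sample_rate = sample_rate,
                center_index = 33L))
  }
  if (any(components$freq_khz * 1000 >= sample_rate / 2))
    stop("component frequency at or above Nyquist")
  sig_ref <- components$sigma_us[which(components$amp_db == 0)][1] * 1e-6
  half <- ceiling(support_sigmas * max(components$sigma_us) * 1e-6 *
                    sample_rate)
  t <- (-half:half) / sample_rate
  x <- numeric(length(t))
  for (i in seq_len(nrow(components))) {
    sig <- components$sigma_us[i] * 1e-6
    gain <- 10^(components$amp_db[i] / 20) * (sig_ref / sig) *
      components$sign[i]
    x <- x + gain * exp(-t^2 / (2 * sig^2)) *
      cos(2 * pi * components$freq_khz[i] * 1000 * t)
  }
  pk <- max(abs(x))
  if (pk > 0) x <- x / pk
  list(samples = x, sample_rate = sample_rate, center_index = half + 1L)
}

# shift all component centres by offset_khz, clamped so the lowest centre
# stays above the feature high-pass and the highest below ~Nyquist margin
.shift_components <- function(components, offset_khz) {
  lo <- 12 - min(components$freq_khz)
  hi <- 240 - max(components$freq_khz)
  components$freq_khz <- components$freq_khz +
    min(max(offset_khz, lo), hi)
  components
}

# draw one event's click schedule; returns a data.frame of click draws
.draw_event_clicks <- function(template, n_clicks, t_start, t_end,
                               event_offset_khz, ici_mode_s) {
  sdlog <- template$ici_dispersion
  mu <- log(ici_mode_s) + sdlog^2          # log-normal parameterised by mode
  ici <- rlnorm(n_clicks - 1, meanlog = mu, sdlog = sdlog)
  times <- t_start + c(0, cumsum(ici))
  keep <- times < t_end
  times <- times[keep]
  n <- length(times)
  offs <- rnorm(n, 0, template$within_event_jitter_sd)
  v <- template$variant
  u <- runif(n)
  shift <- numeric(n)
  up <- u < v$p_up
  dn <- u >= v$p_up & u < v$p_up + v$p_dn
  shift[up] <- runif(sum(up), v$up[1], v$up[2])
  shift[dn] <- -runif(sum(dn), v$dn[1], v$dn[2])
  data.frame(
    time_s = times,
    offset_khz = template$base_offset_khz + event_offset_khz + offs + shift,
    snr_db = runif(n, template$snr_range[1], template$snr_range[2]),
    variant = up | dn)
}

#' Sample one event's click train
#'
#' Draws strictly increasing click times whose intervals are log-normal
#' with mode `ici_mode_s`, plus the event- and click-level frequency
#' offsets, and renders each click waveform.
#'
#' @param template a [species_template()].
#' @param n_clicks number of clicks requested (>= 1).
#' @param sample_rate sampling rate for the rendered waveforms, Hz.
#' @param t_start start time of the train, s.
#' @param event_offset_khz event-level frequency offset; drawn from
#'   `N(0, between_event_jitter_sd)` when `NULL`.
#' @param ici_mode_s inter-click-interval mode for this train; defaults to
#'   the template value.
#' @param render if `FALSE`, skip waveform rendering (schedule only).
#' @return data.frame of click draws with a `waveform` list-column when
#'   rendered.
#' @export
sample_event_clicks <- function(template, n_clicks, sample_rate = 500000,
                                t_start = 0, event_offset_khz = NULL,
                                ici_mode_s = NULL, render = TRUE) {
  stopifnot(n_clicks >= 1)
  if (is.null(event_offset_khz))
    event_offset_khz <- rnorm(1, 0, template$between_event_jitter_sd)
  ici_mode_s <- ici_mode_s %||% template$ici_mode_s
  clicks <- .draw_event_clicks(template, n_clicks, t_start, Inf,
                               event_offset_khz, ici_mode_s)
  if (render) {
    clicks$waveform <- lapply(clicks$offset_khz, function(o) {
      synthesize_click(.shift_components(template$components, o),
                       sample_rate)
    })
  }
  attr(clicks, "event_offset_khz") <- event_offset_khz
  clicks
}

#' Simulation configuration
#'
#' Defaults reproduce the field study design: 19 beluga events across 2
#' encounters with 1-min windows and 62 narwhal events across 5 encounters
#' with 2-min windows, a median of 71 clicks per event, 500 kHz sampling,
#' and recordings partitioned into 5-s segments.
#'
#' @param n_events named events-per-species vector.
#' @param n_encounters named encounters-per-species vector.
#' @param clicks_per_event_median,clicks_per_event_sdlog log-normal click
#'   count distribution per event (rounded, minimum 5).
#' @param window_s named event window length per species, s.
#' @param sample_rate Hz. @param segment_length_s WAV segment length, s.
#' @param noise_sd white-noise standard deviation, linear pressure units.
#' @param seed optional RNG seed used by [generate_dataset()].
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_events = c(beluga = 19, narwhal = 62),
                       n_encounters = c(beluga = 2, narwhal = 5),
                       clicks_per_event_median = 71,
                       clicks_per_event_sdlog = 0.4,
                       window_s = c(beluga = 60, narwhal = 120),
                       sample_rate = 500000,
                       segment_length_s = 5,
                       noise_sd = 1,
                       seed = NULL) {
  stopifnot(all(n_events >= 1), all(n_encounters >= 1),
            clicks_per_event_median >= 1, sample_rate > 0,
            segment_length_s > 0, noise_sd >= 0)
  structure(list(n_events = n_events, n_encounters = n_encounters,
                 clicks_per_event_median = clicks_per_event_median,
                 clicks_per_event_sdlog = clicks_per_event_sdlog,
                 window_s = window_s, sample_rate = sample_rate,
                 segment_length_s = segment_length_s, noise_sd = noise_sd,
                 seed = seed),
            class = "sim_config")
}

#' Generate a synthetic multi-encounter dataset
#'
#' Draws the full event/encounter design: events are distributed
#' round-robin across each species' encounters, each encounter's timeline
#' is tiled into consecutive species-specific windows (one event per
#' window), and every event receives an event-level frequency offset, an
#' event-level ICI mode, and a click schedule.  Waveforms are rendered
#' lazily by [render_event()] / [render_recording()].
#'
#' @param config a [sim_config()].
#' @param templates named list of [species_template()] objects.
#' @return object of class `click_dataset` with `$events` and `$clicks`
#'   data.frames.
#' @export
generate_dataset <- function(config = sim_config(),
                             templates = default_templates()) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  for (tpl in templates) {
    if (config$sample_rate <= 2 * max(tpl$components$freq_khz) * 1000)
      stop("sample_rate must exceed twice the highest template frequency")
    win <- config$window_s[[tpl$species]]
    if (win < 3 * tpl$ici_mode_s)
      stop("event window too short to hold a click train at ici_mode")
  }
  events <- list()
  clicks <- list()
  for (sp in names(config$n_events)) {
    tpl <- templates[[sp]]
    n_ev <- config$n_events[[sp]]
    n_enc <- config$n_encounters[[sp]]
    win <- config$window_s[[sp]]
    enc_of_event <- rep(seq_len(n_enc), length.out = n_ev)
    slot_in_enc <- stats::ave(enc_of_event, enc_of_event,
                              FUN = seq_along) - 1
    ici_sig2 <- log(1 + tpl$ici_event_cv^2)
    for (e in seq_len(n_ev)) {
      enc_id <- sprintf("%s_%d", sp, enc_of_event[e])
      ev_id <- sprintf("%s_e%02d", enc_id, slot_in_enc[e] + 1)
      win_start <- slot_in_enc[e] * win
      n_clicks <- max(5L, as.integer(round(rlnorm(
        1, log(config$clicks_per_event_median),
        config$clicks_per_event_sdlog))))
      ev_off <- rnorm(1, 0, tpl$between_event_jitter_sd)
      ev_ici <- if (tpl$ici_event_cv > 0) {
        rlnorm(1, log(tpl$ici_mode_s) - ici_sig2 / 2, sqrt(ici_sig2))
      } else tpl$ici_mode_s
      t0 <- win_start + runif(1, 0.4, 1.2)
      cl <- .draw_event_clicks(tpl, n_clicks, t0, win_start + win - 0.25,
                               ev_off, ev_ici)
      cl$event_id <- ev_id
      cl$species <- sp
      cl$encounter <- enc_id
      clicks[[ev_id]] <- cl
      events[[ev_id]] <- data.frame(
        event_id = ev_id, species = sp, encounter = enc_id,
        win_start = win_start, win_end = win_start + win,
        n_clicks = nrow(cl), event_offset_khz = ev_off,
        ici_mode_s = ev_ici)
    }
  }
  structure(list(events = do.call(rbind, c(events, make.row.names = FALSE)),
                 clicks = do.call(rbind, c(clicks, make.row.names = FALSE)),
                 templates = templates, config = config),
            class = "click_dataset")
}

#' @export
print.click_dataset <- function(x, ...) {
  cat("Synthetic click dataset:", nrow(x$events), "events,",
      nrow(x$clicks), "clicks\n")
  print(table(x$events$species))
  invisible(x)
}

# TK-energy peak of a unit-amplitude click after boxcar smoothing; used to
# scale clicks so the detector sees the requested SNR over unit noise
.unit_tk_peak <- function(samples, smooth) {
  max(.boxcar_cpp(.tk_energy_cpp(samples), smooth))
}

# render the clicks of `cl` (schedule rows) into noise over [t0, t1).
# Click placement is inlined so the (possibly very large) buffer is
# modified in place rather than copied once per click.
.render_span <- function(cl, templates, t0, t1, sample_rate, noise_sd,
                         smooth = NULL) {
  smooth <- smooth %||% max(1L, round(1e-4 * sample_rate))
  n <- round((t1 - t0) * sample_rate)
  buf <- if (noise_sd > 0) rnorm(n, 0, noise_sd) else numeric(n)
  ref_sd <- if (noise_sd > 0) noise_sd else 1
  for (i in seq_len(nrow(cl))) {
    tpl <- templates[[cl$species[i]]]
    wf <- synthesize_click(
      .shift_components(tpl$components, cl$offset_khz[i]), sample_rate)
    upk <- .unit_tk_peak(wf$samples, smooth)
    gain <- ref_sd * sqrt(10^(cl$snr_db[i] / 10) / upk)
    pos <- round((cl$time_s[i] - t0) * sample_rate) + 1L
    i0 <- pos - (wf$center_index - 1L)
    i1 <- i0 + length(wf$samples) - 1L
    src0 <- max(1L, 1L - i0 + 1L)
    src1 <- length(wf$samples) - max(0L, i1 - n)
    if (src1 < src0) next
    dst <- max(1L, i0):min(n, i1)
    buf[dst] <- buf[dst] + gain * wf$samples[src0:src1]
  }
  buf
}

#' Render one event's recording span
#'
#' Renders white Gaussian noise covering the event's click train (plus a
#' margin, clipped to the event window) and embeds each click scaled so the
#' detector-domain signal-to-noise ratio matches the click's drawn SNR.
#'
#' @param dataset a `click_dataset`.
#' @param event_id one of `dataset$events$event_id`.
#' @param noise_sd noise standard deviation; defaults to the config value.
#' @param margin_s rendered margin around the first/last click, s.
#' @return list with `samples`, `t0` (absolute start time, s),
#'   `sample_rate`, `encounter`, `species`.
#' @export
render_event <- function(dataset, event_id, noise_sd = NULL,
                         margin_s = 0.25) {
  noise_sd <- noise_sd %||% dataset$config$noise_sd
  ev <- dataset$events[dataset$events$event_id == event_id, ]
  if (nrow(ev) != 1) stop("unknown event_id: ", event_id)
  cl <- dataset$clicks[dataset$clicks$event_id == event_id, ]
  sr <- dataset$config$sample_rate
  t0 <- max(ev$win_start, min(cl$time_s) - margin_s)
  t1 <- min(ev$win_end, max(cl$time_s) + margin_s)
  list(samples = .render_span(cl, dataset$templates, t0, t1, sr, noise_sd),
       t0 = t0, sample_rate = sr,
       encounter = ev$encounter, species = ev$species)
}

#' Render an encounter as fixed-length segments
#'
#' Partitions an encounter's timeline into `segment_length_s` blocks (the
#' lossless 5-s file convention of field recorders) and renders the
#' requested segments: white noise plus every scheduled click.  Beware of
#' memory: a full default encounter is minutes of 500 kHz audio, so select
#' `segments` or use a reduced [sim_config()] for exports.
#'
#' @param dataset a `click_dataset`.
#' @param encounter encounter id (e.g. `"beluga_1"`).
#' @param segments integer vector of 1-based segment indices; `NULL` = all.
#' @param noise_sd noise sd; defaults to the config value.
#' @return list with `blocks` (list of sample vectors), `segment_starts_s`,
#'   `sample_rate`.
#' @export
render_recording <- function(dataset, encounter, segments = NULL,
                             noise_sd = NULL) {
  noise_sd <- noise_sd %||% dataset$config$noise_sd
  stopifnot(noise_sd >= 0)
  ev <- dataset$events[dataset$events$encounter == encounter, ]
  if (nrow(ev) == 0) stop("unknown encounter: ", encounter)
  sr <- dataset$config$sample_rate
  seg <- dataset$config$segment_length_s
  total_s <- max(ev$win_end)
  n_seg <- ceiling(total_s / seg)
  if (is.null(segments)) segments <- seq_len(n_seg)
  cl <- dataset$clicks[dataset$clicks$encounter == encounter, ]
  blocks <- lapply(segments, function(k) {
    t0 <- (k - 1) * seg
    t1 <- t0 + seg
    # clicks whose support can touch this segment
    near <- cl[cl$time_s > t0 - 0.01 & cl$time_s < t1 + 0.01, ]
    .render_span(near, dataset$templates, t0, t1, sr, noise_sd)
  })
  list(blocks = blocks, segment_starts_s = (segments - 1) * seg,
       sample_rate = sr)
}
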