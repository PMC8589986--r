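# Event building: clicks are assigned to predetermined, consecutive time
# windows anchored at each recording's first sample (1 min for beluga,
# 2 min for narwhal recordings), and each event is summarised by the mean
# of every click parameter except the inter-click interval, which uses a
# histogram-approximated mode.

#' Assign detections to fixed-window acoustic events
#'
#' Tiles the recording time axis into consecutive `window_s` windows and
#' assigns each click to the window containing its time (half-open
#' `[start, end)` windows, anchored at 0).  Windows without clicks simply
#' never appear.
#'
#' @param clicks data.frame with a `time_s` column (and optionally an
#'   `encounter` column: windows are tiled per encounter).
#' @param window_s window length in seconds.
#' @return the input with `event_window` (integer index), `win_start_s`
#'   and `event_id` columns added.
#' @export
assign_events <- function(clicks, window_s) {
  stopifnot(window_s > 0, is.data.frame(clicks), "time_s" %in% names(clicks))
  k <- floor(clicks$time_s / window_s)
  clicks$event_window <- as.integer(k)
  clicks$win_start_s <- k * window_s
  enc <- if ("encounter" %in% names(clicks)) clicks$encounter else "rec"
  clicks$event_id <- sprintf("%s_e%02d", enc, k + 1)
  clicks
}

#' Mode of the inter-click intervals of a click train
#'
#' Successive differences of the click times are binned into a fixed-width
#' histogram whose bins are centred on multiples of `bin_s` (10 ms by
#' default), and the mode is approximated by the centre of the most
#' populated bin, ties broken toward the smaller interval.  Centred bins
#' make the estimator exact for trains with a constant inter-click
#' interval that is a multiple of the bin width.
#'
#' @param click_times_s sorted click times, s (>= 2 values required).
#' @param bin_s histogram bin width, s.
#' @return the approximated modal inter-click interval, s (`NA` with fewer
#'   than 2 clicks).
#' @export
ici_mode <- function(click_times_s, bin_s = 0.01) {
  if (length(click_times_s) < 2) return(NA_real_)
  d <- diff(sort(click_times_s))
  k <- floor(d / bin_s + 0.5)
  kk <- sort(unique(k))                    # ascending: ties pick smallest
  counts <- vapply(kk, function(z) sum(k == z), numeric(1))
  kk[which.max(counts)] * bin_s
}

#' Summarise one event's clicks into a feature row
#'
#' Arithmetic mean of each click-level parameter over the member clicks
#' (`NA`s dropped), except `ici`, which is replaced by the event's modal
#' inter-click interval.
#'
#' @param event_clicks data.frame of one event's click features (the 20
#'   parameter columns plus `time_s`).
#' @return named numeric vector of the 20 event-level features.
#' @export
event_feature_summary <- function(event_clicks) {
  vals <- vapply(.feature_names, function(v) {
    mean(event_clicks[[v]], na.rm = TRUE)
  }, numeric(1))
  vals["ici"] <- ici_mode(event_clicks$time_s)
  vals
}

#' Build the event feature table
#'
#' Groups click-level features by event and reduces each event to its mean
#' parameter vector (modal ICI).  Events with fewer than `min_clicks`
#' clicks, or whose ICI mode is undefined, are excluded with a message.
#'
#' @param clicks data.frame of click features carrying `event_id`,
#'   `time_s`, the 20 parameter columns, and optionally `species` and
#'   `encounter` labels.
#' @param min_clicks minimum event size (default 2, the smallest size with
#'   a defined inter-click interval).
#' @return data.frame: one row per retained event with `event_id`,
#'   `species`, `encounter`, `n_clicks` and the 20 feature columns.
#' @export
build_event_table <- function(clicks, min_clicks = 2) {
  stopifnot("event_id" %in% names(clicks))
  ids <- unique(clicks$event_id)
  rows <- vector("list", length(ids))
  dropped <- character()
  for (i in seq_along(ids)) {
    ec <- clicks[clicks$event_id == ids[i], ]
    if (nrow(ec) < min_clicks) {
      dropped <- c(dropped, ids[i])
      next
    }
    f <- event_feature_summary(ec)
    if (is.na(f["ici"])) {
      dropped <- c(dropped, ids[i])
      next
    }
    meta <- data.frame(
      event_id = ids[i],
      species = if ("species" %in% names(ec)) ec$species[1] else NA,
      encounter = if ("encounter" %in% names(ec)) ec$encounter[1] else NA,
      n_clicks = nrow(ec))
    rows[[i]] <- cbind(meta, as.data.frame(as.list(f)))
  }
  if (length(dropped))
    message("excluded ", length(dropped),
            " event(s) below the minimum size: ",
            paste(dropped, collapse = ", "))
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}
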