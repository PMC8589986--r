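# End-to-end pipeline: simulate -> render -> detect -> extract -> events
# -> statistics -> classifiers, plus a small subcommand CLI.

#' Run the detection and feature-extraction front end on a dataset
#'
#' Renders each simulated event's recording span (white noise plus clicks),
#' runs the click detector over it, extracts the twenty parameters per
#' detection, and tags every click with its event window, species and
#' encounter.  Rendering is per event span rather than per whole encounter
#' so minutes of silent 500 kHz audio are not materialised; the detector's
#' false-alarm behaviour on pure noise is validated separately.
#'
#' @param dataset a `click_dataset` from [generate_dataset()].
#' @param detector a [detector_config()].
#' @param progress print per-event progress.
#' @return click feature data.frame (one row per detection) with labels.
#' @export
pipeline_click_features <- function(dataset, detector = detector_config(),
                                    progress = FALSE) {
  out <- vector("list", nrow(dataset$events))
  for (i in seq_len(nrow(dataset$events))) {
    ev <- dataset$events[i, ]
    rec <- render_event(dataset, ev$event_id)
    det <- detect_clicks(rec$samples, rec$sample_rate,
                         config = detector, t0 = rec$t0)
    if (nrow(det$detections) == 0) next
    feats <- extract_click_features(det)
    feats <- assign_events(cbind(feats, encounter = ev$encounter),
                           dataset$config$window_s[[ev$species]])
    # keep only detections inside this event's window (stray false alarms
    # in the rendered margin would otherwise leak into a neighbour window)
    feats <- feats[feats$event_id == ev$event_id, ]
    if (nrow(feats) == 0) next
    feats$species <- ev$species
    out[[i]] <- feats
    if (progress) message(ev$event_id, ": ", nrow(feats), " clicks")
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(res) <- NULL
  res
}

#' Run the full analysis pipeline
#'
#' Simulates (or accepts) a dataset, runs detection and feature extraction,
#' builds the event table, and executes the requested analysis stages:
#' multivariate statistics, the single balanced random forest, the
#' two-stage classifier, and the encounter-similarity validation.
#'
#' @param config a [sim_config()]; `config$seed` drives all randomness.
#' @param templates species templates.
#' @param stages subset of `c("stats", "rf", "banter", "encounters")`.
#' @param rf_ntree,banter_ntree1,banter_ntree2,encounter_ntree forest sizes.
#' @param out_dir if non-`NULL`, write CSV/JSON artifacts there.
#' @param progress print progress messages.
#' @return list with `click_features`, `event_table`, and one element per
#'   executed stage, plus a `provenance` block.
#' @export
run_pipeline <- function(config = sim_config(),
                         templates = default_templates(),
                         stages = c("stats", "rf", "banter"),
                         rf_ntree = 10000, banter_ntree1 = 20000,
                         banter_ntree2 = 20000, encounter_ntree = 10000,
                         out_dir = NULL, progress = FALSE) {
  dataset <- generate_dataset(config, templates)
  clicks <- pipeline_click_features(dataset, progress = progress)
  event_table <- build_event_table(clicks)
  out <- list(click_features = clicks, event_table = event_table)

  if ("stats" %in% stages) {
    d <- zscore_and_distance(event_table)
    out$stats <- list(
      permanova = permanova(d, event_table$species),
      permdisp = permdisp(d, event_table$species),
      pca = pca_broken_stick(event_table))
  }
  if ("rf" %in% stages) {
    out$rf <- fit_balanced_forest(
      event_table[, .feature_names], event_table$species,
      ntree = rf_ntree, importance = TRUE, proximity = TRUE,
      oob_trace = TRUE)
  }
  if ("banter" %in% stages) {
    out$banter <- fit_banter(clicks, ntree1 = banter_ntree1,
                             ntree2 = banter_ntree2)
  }
  if ("encounters" %in% stages) {
    out$encounters <- encounter_similarity(clicks, ntree = encounter_ntree)
  }
  out$provenance <- list(
    seed = config$seed,
    config = config[!vapply(config, is.null, logical(1))],
    package_version = as.character(utils::packageVersion("echoclass")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC"))

  if (!is.null(out_dir)) .write_pipeline_artifacts(out, out_dir)
  out
}

.write_pipeline_artifacts <- function(out, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(out$click_features,
            file.path(out_dir, "click_features.csv"), row.names = FALSE)
  write.csv(out$event_table, file.path(out_dir, "event_table.csv"),
            row.names = FALSE)
  summary <- list(provenance = out$provenance,
                  n_events = nrow(out$event_table),
                  n_clicks = nrow(out$click_features))
  if (!is.null(out$stats)) {
    summary$stats <- list(
      permanova = out$stats$permanova[c("statistic", "p_value",
                                        "df_between", "df_within")],
      permdisp = c(out$stats$permdisp[c("statistic", "p_value")],
                   list(group_dispersion =
                          as.list(out$stats$permdisp$group_dispersion))),
      pca = list(proportion = out$stats$pca$proportion,
                 broken_stick = out$stats$pca$broken_stick,
                 significant = which(out$stats$pca$significant)))
  }
  if (!is.null(out$rf)) {
    summary$rf <- list(confusion = out$rf$confusion,
                       rates = out$rf$summary)
    write.csv(out$rf$importance, file.path(out_dir, "rf_importance.csv"),
              row.names = FALSE)
    mds <- proximity_mds(out$rf)
    write.csv(data.frame(event_id = out$event_table$event_id, mds$points),
              file.path(out_dir, "rf_mds.csv"), row.names = FALSE)
    write.csv(data.frame(tree = seq_along(out$rf$oob_trace),
                         oob_error = out$rf$oob_trace),
              file.path(out_dir, "rf_oob_trace.csv"), row.names = FALSE)
  }
  if (!is.null(out$banter)) {
    summary$banter <- list(
      detectors = out$banter$call_stage$detectors,
      event_confusion = out$banter$event_stage$confusion,
      event_rates = out$banter$event_stage$summary)
    write.csv(out$banter$event_features,
              file.path(out_dir, "banter_event_features.csv"),
              row.names = FALSE)
  }
  if (!is.null(out$encounters)) {
    write.csv(out$encounters, file.path(out_dir, "encounter_similarity.csv"),
              row.names = FALSE)
    summary$encounters <- out$encounters
  }
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(out_dir)
}

#' Command-line entry point
#'
#' Subcommand interface over [run_pipeline()]:
#' `simulate`, `stats`, `classify-rf`, `classify-banter`, `encounters`,
#' `run-all`.  Flags: `--seed`, `--out-dir`, `--events-beluga`,
#' `--events-narwhal`, `--clicks`, `--ntree`.
#'
#' @param args character vector (defaults to the command line).
#' @return invisibly, the pipeline result.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0) {
    cat("usage: echoclass <simulate|stats|classify-rf|classify-banter|",
        "encounters|run-all> [--seed N] [--out-dir DIR]\n",
        "       [--events-beluga N] [--events-narwhal N] [--clicks N]",
        " [--ntree N]\n", sep = "")
    return(invisible(NULL))
  }
  cmd <- args[1]
  opt <- function(flag, default) {
    i <- which(args == flag)
    if (length(i) && i < length(args)) args[i + 1] else default
  }
  seed <- as.integer(opt("--seed", 1))
  out_dir <- opt("--out-dir", NULL)
  ntree <- as.integer(opt("--ntree", 2000))
  cfg <- sim_config(
    n_events = c(beluga = as.integer(opt("--events-beluga", 19)),
                 narwhal = as.integer(opt("--events-narwhal", 62))),
    clicks_per_event_median = as.integer(opt("--clicks", 71)),
    seed = seed)
  stages <- switch(cmd,
                   simulate = character(),
                   stats = "stats",
                   `classify-rf` = "rf",
                   `classify-banter` = "banter",
                   encounters = "encounters",
                   `run-all` = c("stats", "rf", "banter", "encounters"),
                   stop("unknown subcommand: ", cmd))
  res <- run_pipeline(cfg, stages = stages, rf_ntree = ntree,
                      banter_ntree1 = ntree, banter_ntree2 = ntree,
                      encounter_ntree = ntree, out_dir = out_dir)
  cat("events:", nrow(res$event_table), " clicks:",
      nrow(res$click_features), "\n")
  if (!is.null(res$rf)) {
    cat("RF OOB overall: ",
        res$rf$summary$rate_pct[res$rf$summary$class == "Overall"], "%\n")
  }
  if (!is.null(res$banter)) {
    s <- res$banter$event_stage$summary
    cat("Two-stage OOB overall: ",
        s$rate_pct[s$class == "Overall"], "%\n")
  }
  invisible(res)
}
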