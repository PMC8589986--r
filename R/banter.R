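# Two-stage event classification (call classifier + event classifier).
# Stage 1 fits one balanced forest per click detector on the 20 click-level
# parameters; its OOB assignment probabilities and the per-event detector
# proportions, plus the event's modal inter-click interval, become the
# predictors of the stage-2 event forest.

# impute missing click-level ICIs (first click of each train) with the
# event's median ICI so the forests see a complete matrix
.impute_ici <- function(clicks) {
  overall <- median(clicks$ici, na.rm = TRUE)
  for (ev in unique(clicks$event_id[is.na(clicks$ici)])) {
    idx <- clicks$event_id == ev
    m <- median(clicks$ici[idx], na.rm = TRUE)
    clicks$ici[idx & is.na(clicks$ici)] <- if (is.finite(m)) m else overall
  }
  clicks
}

#' Fit the stage-1 call classifiers
#'
#' One balanced forest per detector, trained on all clicks routed to that
#' detector.  Detectors with fewer than `sampsize` clicks in either species
#' are dropped for insufficient data.  Per-click species assignment
#' probabilities are taken from out-of-bag votes only, so no training
#' information leaks into stage 2.
#'
#' @param clicks click feature data.frame with `event_id`, `species`,
#'   `detector_code`, `time_s` and the 20 parameter columns.
#' @param sampsize clicks drawn per species per tree (without replacement);
#'   by default also the retention threshold per detector.
#' @param ntree trees per detector forest.
#' @param mtry default `floor(sqrt(20))`.
#' @param importance compute stage-1 permutation importance (costly for
#'   large click sets; off by default).
#' @param min_clicks per-species click minimum for a detector to be
#'   retained (defaults to `sampsize`).
#' @param adaptive if `TRUE`, each detector's per-tree sample is reduced to
#'   half its smaller class (capped at `sampsize`), for small training sets
#'   such as single-encounter pairs.
#' @return object of class `call_stage`: `models` (per retained detector),
#'   `event_features` (stage-2 predictor table), `detectors`, `dropped`.
#' @export
fit_call_stage <- function(clicks, sampsize = 50, ntree = 20000,
                           mtry = NULL, importance = FALSE,
                           min_clicks = sampsize, adaptive = FALSE) {
  stopifnot(all(c("event_id", "species", "detector_code", "time_s")
                %in% names(clicks)))
  clicks <- .impute_ici(clicks)
  species <- sort(unique(as.character(clicks$species)))
  if (length(species) != 2) stop("need exactly two species")
  tab <- table(clicks$detector_code, clicks$species)
  codes <- as.integer(rownames(tab))
  retained <- codes[apply(tab >= min_clicks, 1, all)]
  retained <- sort(retained[retained > 0])
  dropped <- setdiff(codes, retained)
  if (length(retained) < 2)
    stop("fewer than two detectors have ", min_clicks,
         " clicks in both species")

  models <- list()
  oob_prob <- matrix(NA_real_, nrow(clicks), 1)
  for (code in retained) {
    idx <- which(clicks$detector_code == code)
    sub <- clicks[idx, ]
    ss <- if (adaptive) {
      min(sampsize, floor(min(table(sub$species)) / 2))
    } else sampsize
    fit <- fit_balanced_forest(sub[, .feature_names], sub$species,
                               mtry = mtry, sampsize = ss,
                               ntree = ntree, importance = importance,
                               keep_forest = TRUE)
    models[[as.character(code)]] <- fit
    oob_prob[idx, 1] <- fit$vote_fraction[, species[1]]
  }

  ef <- .assemble_event_features(clicks, retained, species, oob_prob[, 1])
  structure(list(models = models, event_features = ef,
                 detectors = retained, dropped = dropped,
                 species = species, sampsize = sampsize),
            class = "call_stage")
}

# Build the stage-2 predictor table.  prob1 is P(species[1]) per click
# (OOB during training, full-forest for prediction).  Events with no
# clicks in a detector get proportion 0 and the neutral probability 0.5.
.assemble_event_features <- function(clicks, retained, species, prob1) {
  events <- unique(clicks$event_id)
  rows <- lapply(events, function(ev) {
    idx <- clicks$event_id == ev
    ec <- clicks[idx, ]
    pr <- prob1[idx]
    in_ret <- ec$detector_code %in% retained
    n_ret <- sum(in_ret)
    row <- list(event_id = ev)
    if ("species" %in% names(ec)) row$species <- ec$species[1]
    if ("encounter" %in% names(ec)) row$encounter <- ec$encounter[1]
    for (code in retained) {
      sel <- ec$detector_code == code
      row[[sprintf("prop_d%d", code)]] <-
        if (n_ret > 0) sum(sel) / n_ret else 0
      p <- if (any(sel)) mean(pr[sel], na.rm = TRUE) else 0.5
      if (is.na(p)) p <- 0.5
      row[[sprintf("pr_%s_d%d", species[1], code)]] <- p
      row[[sprintf("pr_%s_d%d", species[2], code)]] <- 1 - p
    }
    row$ici <- ici_mode(ec$time_s)
    row$n_retained_clicks <- n_ret
    as.data.frame(row)
  })
  do.call(rbind, rows)
}

#' Fit the stage-2 event classifier
#'
#' A single balanced forest on the stage-1 event features (mean assignment
#' probabilities and detector proportions per retained detector, plus the
#' event ICI mode).
#'
#' @param event_features output table of [fit_call_stage()].
#' @param sampsize events per species per tree.
#' @param ntree,mtry forest parameters (`mtry` defaults to the square root
#'   of the predictor count).
#' @param importance compute permutation importance (cheap here).
#' @return a `balanced_rf` for events.
#' @export
fit_event_stage <- function(event_features, sampsize = 9, ntree = 20000,
                            mtry = NULL, importance = TRUE) {
  pred_cols <- setdiff(names(event_features),
                       c("event_id", "species", "encounter",
                         "n_retained_clicks"))
  ef <- event_features
  ef$ici[is.na(ef$ici)] <- median(ef$ici, na.rm = TRUE)
  fit_balanced_forest(ef[, pred_cols], ef$species, mtry = mtry,
                      sampsize = sampsize, ntree = ntree,
                      importance = importance, oob_trace = FALSE)
}

#' Fit a full two-stage classifier
#'
#' @inheritParams fit_call_stage
#' @param min_clicks1,adaptive stage-1 retention/sampling controls, see
#'   [fit_call_stage()].
#' @param sampsize1,ntree1 stage-1 (call) forest parameters.
#' @param sampsize2,ntree2 stage-2 (event) forest parameters.
#' @return object of class `banter_model` with `call_stage`, `event_stage`
#'   and the event feature table.
#' @export
fit_banter <- function(clicks, sampsize1 = 50, ntree1 = 20000,
                       sampsize2 = 9, ntree2 = 20000, mtry = NULL,
                       min_clicks1 = sampsize1, adaptive = FALSE) {
  cs <- fit_call_stage(clicks, sampsize = sampsize1, ntree = ntree1,
                       mtry = mtry, min_clicks = min_clicks1,
                       adaptive = adaptive)
  es <- fit_event_stage(cs$event_features, sampsize = sampsize2,
                        ntree = ntree2, mtry = mtry)
  structure(list(call_stage = cs, event_stage = es,
                 event_features = cs$event_features),
            class = "banter_model")
}

#' @export
print.banter_model <- function(x, ...) {
  cat("Two-stage classifier; detectors:",
      paste(x$call_stage$detectors, collapse = ", "), "\n")
  cat("Event-stage OOB summary:\n")
  print(x$event_stage$summary, digits = 4)
  invisible(x)
}

#' Predict species for new events with a fitted two-stage model
#'
#' Stage-1 probabilities for the new clicks come from the fitted call
#' forests (all trees); event features are assembled exactly as in
#' training; the event forest returns a vote distribution per event.
#' Events with no clicks in any retained detector are flagged
#' unclassifiable (`NA` prediction) rather than silently dropped.  Vote
#' ties resolve to the alphabetically first species.
#'
#' @param model a `banter_model`.
#' @param clicks click feature table for the new events (same columns as
#'   training, `species` not required).
#' @return data.frame: `event_id`, `predicted`, one vote column per
#'   species, `n_retained_clicks`.
#' @export
predict_events <- function(model, clicks) {
  cs <- model$call_stage
  clicks <- .impute_ici(clicks)
  prob1 <- rep(NA_real_, nrow(clicks))
  for (code in cs$detectors) {
    idx <- which(clicks$detector_code == code)
    if (!length(idx)) next
    pr <- predict(cs$models[[as.character(code)]],
                  clicks[idx, .feature_names], type = "prob")
    prob1[idx] <- pr[, cs$species[1]]
  }
  keep_species <- "species" %in% names(clicks)
  ef <- .assemble_event_features(clicks, cs$detectors, cs$species, prob1)
  pred_cols <- model$event_stage$feature_names
  ef$ici[is.na(ef$ici)] <- median(ef$ici, na.rm = TRUE)
  votes <- predict(model$event_stage, ef[, pred_cols], type = "prob")
  predicted <- factor(cs$species[ifelse(votes[, 2] > votes[, 1], 2, 1)],
                      levels = cs$species)
  predicted[ef$n_retained_clicks == 0] <- NA
  if (any(ef$n_retained_clicks == 0))
    warning(sum(ef$n_retained_clicks == 0),
            " event(s) had no clicks in a retained detector and were",
            " flagged unclassifiable")
  out <- data.frame(event_id = ef$event_id, predicted = predicted)
  if (keep_species) out$observed <- ef$species
  out[[paste0("vote_", cs$species[1])]] <- votes[, 1]
  out[[paste0("vote_", cs$species[2])]] <- votes[, 2]
  out$n_retained_clicks <- ef$n_retained_clicks
  out
}

#' Encounter-similarity validation
#'
#' For every (beluga encounter, narwhal encounter) pair, a two-stage model
#' is trained on that pair's events only and used to predict all held-out
#' events.  The training (OOB) and validation confusion matrices are
#' row-normalised and correlated; a correlation above `threshold` flags
#' the encounters as similar.  With two classes the per-class correct-rate
#' vectors are degenerate under Pearson correlation, so the default
#' correlates all four row-normalised confusion cells (see the methods
#' vignette).
#'
#' @param clicks click feature table with `species`, `encounter`,
#'   `event_id`, `detector_code`, `time_s` and the 20 parameters.
#' @param ntree trees for both stages of each pair model.
#' @param sampsize1 stage-1 per-class sample cap (reduced per detector to
#'   half the smaller class when clicks are scarce; detectors under
#'   `min_detector_clicks` per species are dropped for that pair).
#' @param min_detector_clicks per-species click minimum for a detector to
#'   be retained in a pair model.
#' @param method correlation variant: `"cells"` (Pearson over the 4
#'   row-normalised cells), `"rates"` (per-class correct rates; degenerate,
#'   provided for completeness), or `"spearman"` (rank correlation over
#'   cells).
#' @param threshold similarity threshold on the correlation.
#' @return data.frame: one row per encounter pair with `correlation` and
#'   `similar`; confusion matrices attached as the `"confusions"`
#'   attribute.
#' @export
encounter_similarity <- function(clicks, ntree = 10000, sampsize1 = 50,
                                 min_detector_clicks = 10,
                                 method = c("cells", "rates", "spearman"),
                                 threshold = 0.5) {
  method <- match.arg(method)
  stopifnot(all(c("species", "encounter", "event_id") %in% names(clicks)))
  species <- sort(unique(as.character(clicks$species)))
  enc1 <- unique(clicks$encounter[clicks$species == species[1]])
  enc2 <- unique(clicks$encounter[clicks$species == species[2]])
  pairs <- expand.grid(a = enc1, b = enc2, stringsAsFactors = FALSE)
  res <- list()
  confusions <- list()
  for (i in seq_len(nrow(pairs))) {
    train_enc <- c(pairs$a[i], pairs$b[i])
    tr <- clicks[clicks$encounter %in% train_enc, ]
    te <- clicks[!clicks$encounter %in% train_enc, ]
    ev_counts <- table(unique(tr[, c("event_id", "species")])$species)
    ss2 <- max(2, floor(min(ev_counts) / 2))
    model <- fit_banter(tr, sampsize1 = sampsize1, ntree1 = ntree,
                        sampsize2 = ss2, ntree2 = ntree,
                        min_clicks1 = min_detector_clicks, adaptive = TRUE)
    train_conf <- model$event_stage$confusion
    pred <- predict_events(model, te)
    valid_conf <- table(factor(pred$observed, levels = species),
                        factor(pred$predicted, levels = species))
    r <- .confusion_correlation(train_conf, valid_conf, method)
    res[[i]] <- data.frame(
      encounter_1 = pairs$a[i], encounter_2 = pairs$b[i],
      correlation = r, similar = is.finite(r) && r > threshold)
    confusions[[i]] <- list(train = train_conf, validation = valid_conf)
  }
  out <- do.call(rbind, res)
  attr(out, "confusions") <- confusions
  out
}

.confusion_correlation <- function(train, valid, method) {
  norm <- function(m) {
    m <- as.matrix(m)
    sweep(m, 1, pmax(rowSums(m), 1), "/")
  }
  a <- norm(train)
  b <- norm(valid)
  switch(method,
         cells = cor(as.vector(a), as.vector(b)),
         rates = cor(diag(a), diag(b)),
         spearman = cor(as.vector(a), as.vector(b), method = "spearman"))
}
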