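# R interface to the balanced random forest.  Each tree draws an equal
# per-class subsample WITHOUT replacement (sampsize rows per class), so the
# classifier is not biased toward the dominant class of an unbalanced
# event set.  OOB predictions are majority votes over the trees in which an
# observation was out-of-bag.

#' Fit a balanced two-class random forest
#'
#' @param x numeric matrix or data.frame of predictors.
#' @param y two-level factor (or coercible) of class labels.
#' @param mtry predictors tried at each split; default
#'   `floor(sqrt(ncol(x)))`.
#' @param sampsize rows drawn per class for each tree, without replacement;
#'   default half the smallest class size.
#' @param ntree number of trees.
#' @param importance compute OOB permutation importance (mean decrease in
#'   OOB accuracy when a predictor is permuted within each tree's OOB set).
#' @param proximity accumulate the N x N proximity matrix (fraction of
#'   trees in which two rows share a terminal node, over all rows).
#' @param oob_trace record the cumulative OOB error after each tree.
#' @param keep_forest keep the trees (needed for [predict()] on new data).
#' @return object of class `balanced_rf` with OOB votes, predictions,
#'   confusion summary (see [classification_summary()]), and optional
#'   importance / proximity / trace components.
#' @export
fit_balanced_forest <- function(x, y, mtry = NULL, sampsize = NULL,
                                ntree = 10000, importance = FALSE,
                                proximity = FALSE, oob_trace = FALSE,
                                keep_forest = TRUE) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- factor(y)
  if (nlevels(y) != 2) stop("y must have exactly two classes")
  counts <- table(y)
  if (is.null(sampsize)) sampsize <- max(1, floor(min(counts) / 2))
  if (length(sampsize) == 1) sampsize <- rep(sampsize, 2)
  if (any(sampsize > counts))
    stop("sampsize exceeds a class size (", min(counts), ")")
  if (is.null(mtry)) mtry <- max(1, floor(sqrt(ncol(x))))
  if (mtry < 1 || mtry > ncol(x)) stop("mtry must be in 1..ncol(x)")

  fit <- .rf_fit_cpp(x, as.integer(y) - 1L, as.integer(ntree),
                     as.integer(mtry), as.integer(sampsize),
                     keep_forest, importance, proximity, oob_trace)

  votes <- fit$votes
  colnames(votes) <- levels(y)
  total <- rowSums(votes)
  oob_pred <- factor(levels(y)[ifelse(votes[, 2] > votes[, 1], 2, 1)],
                     levels = levels(y))
  oob_pred[total == 0] <- NA
  confusion <- table(observed = y, predicted = oob_pred)
  vote_frac <- votes / pmax(total, 1)

  imp <- NULL
  if (importance) {
    imp <- data.frame(variable = colnames(x),
                      mean_decrease_accuracy = fit$importance,
                      sd = fit$importance_sd)
    imp <- imp[order(-imp$mean_decrease_accuracy), ]
    rownames(imp) <- NULL
  }

  structure(list(
    levels = levels(y), y = y, mtry = mtry, sampsize = sampsize,
    ntree = ntree, votes = votes, vote_fraction = vote_frac,
    oob_prediction = oob_pred, confusion = unclass(confusion),
    summary = classification_summary(unclass(confusion)),
    importance = imp, proximity = fit$proximity,
    oob_trace = fit$oob_trace, inbag_count = fit$inbag_count,
    forest = fit$forest, feature_names = colnames(x)),
    class = "balanced_rf")
}

#' @export
print.balanced_rf <- function(x, ...) {
  cat(sprintf("Balanced random forest: %d trees, mtry %d, sampsize %d/class\n",
              x$ntree, x$mtry, x$sampsize[1]))
  print(x$confusion)
  print(x$summary, digits = 4)
  invisible(x)
}

#' Predict with a fitted balanced forest
#'
#' @param object a `balanced_rf` with `keep_forest = TRUE`.
#' @param newdata matrix/data.frame with the training columns.
#' @param type `"response"` for labels, `"prob"` for vote fractions.
#' @param ... unused.
#' @return factor of labels or matrix of class vote fractions.
#' @export
predict.balanced_rf <- function(object, newdata,
                                type = c("response", "prob"), ...) {
  type <- match.arg(type)
  if (is.null(object$forest)) stop("model was fitted with keep_forest = FALSE")
  newdata <- as.matrix(newdata[, object$feature_names, drop = FALSE])
  storage.mode(newdata) <- "double"
  pr <- .rf_predict_cpp(object$forest, newdata)
  colnames(pr) <- object$levels
  if (type == "prob") return(pr)
  factor(object$levels[ifelse(pr[, 2] > pr[, 1], 2, 1)],
         levels = object$levels)
}

#' Classification rates with exact binomial inference
#'
#' Per-class and overall correct classification rates from a confusion
#' matrix (a-priori classes in rows, predictions in columns), with exact
#' Clopper-Pearson 95% confidence intervals and a one-sided exact binomial
#' p-value against the 50% chance rate.
#'
#' @param confusion square count matrix (rows = observed, columns =
#'   predicted, same order).
#' @param conf_level confidence level for the interval.
#' @param chance null success probability for the one-sided test.
#' @return data.frame with one row per class plus an `Overall` row:
#'   `n_correct`, `n_total`, `rate_pct`, `ci_lo_pct`, `ci_hi_pct`,
#'   `p_value`.
#' @export
classification_summary <- function(confusion, conf_level = 0.95,
                                   chance = 0.5) {
  confusion <- as.matrix(confusion)
  stopifnot(nrow(confusion) == ncol(confusion),
            all(confusion >= 0), all(confusion == round(confusion)))
  rows <- c(rownames(confusion) %||% paste0("class", seq_len(nrow(confusion))),
            "Overall")
  correct <- c(diag(confusion), sum(diag(confusion)))
  totals <- c(rowSums(confusion), sum(confusion))
  out <- data.frame(class = rows, n_correct = correct, n_total = totals,
                    rate_pct = NA_real_, ci_lo_pct = NA_real_,
                    ci_hi_pct = NA_real_, p_value = NA_real_)
  for (i in seq_len(nrow(out))) {
    if (out$n_total[i] == 0) next
    bt <- binom.test(out$n_correct[i], out$n_total[i], p = chance,
                     alternative = "greater", conf.level = conf_level)
    ci <- binom.test(out$n_correct[i], out$n_total[i],
                     conf.level = conf_level)$conf.int
    out$rate_pct[i] <- 100 * out$n_correct[i] / out$n_total[i]
    out$ci_lo_pct[i] <- 100 * ci[1]
    out$ci_hi_pct[i] <- 100 * ci[2]
    out$p_value[i] <- bt$p.value
  }
  rownames(out) <- NULL
  out
}

#' OOB accuracy over an mtry x sampsize grid
#'
#' Refits the balanced forest for every combination of `mtry` and
#' `sampsize` and records the overall OOB correct classification rate, to
#' check that the classifier is insensitive to its two tuning parameters.
#'
#' @inheritParams fit_balanced_forest
#' @param mtry_range,sampsize_range integer vectors (defaults 2..19 and
#'   2..18, the full legal ranges for 20 predictors and a smallest class of
#'   19 events).
#' @param ntree trees per grid cell; the default is reduced relative to the
#'   final model since the grid only needs rate stability.
#' @return matrix of OOB overall accuracy (%), mtry in rows, sampsize in
#'   columns.
#' @export
sensitivity_grid <- function(x, y, mtry_range = 2:19,
                             sampsize_range = 2:18, ntree = 500) {
  acc <- matrix(NA_real_, length(mtry_range), length(sampsize_range),
                dimnames = list(mtry = mtry_range, sampsize = sampsize_range))
  for (i in seq_along(mtry_range)) {
    for (j in seq_along(sampsize_range)) {
      fit <- fit_balanced_forest(x, y, mtry = mtry_range[i],
                                 sampsize = sampsize_range[j],
                                 ntree = ntree, keep_forest = FALSE)
      acc[i, j] <- fit$summary$rate_pct[fit$summary$class == "Overall"]
    }
  }
  acc
}

#' Proximity multidimensional scaling
#'
#' Classical MDS of `1 - proximity` (proximity = fraction of trees in
#' which two events share a terminal node), with the percentage of
#' variation carried by each dimension.
#'
#' @param model a `balanced_rf` fitted with `proximity = TRUE`.
#' @param k number of dimensions.
#' @return list with `points` (n x k coordinates) and `explained_pct`.
#' @export
proximity_mds <- function(model, k = 2) {
  if (is.null(model$proximity)) stop("fit with proximity = TRUE")
  d <- 1 - model$proximity
  diag(d) <- 0
  mds <- cmdscale(as.dist(d), k = k, eig = TRUE)
  pos <- mds$eig[mds$eig > 0]
  list(points = mds$points,
       explained_pct = 100 * mds$eig[seq_len(k)] / sum(pos))
}
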