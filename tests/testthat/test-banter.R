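# Two-stage classifier: stage-1 features, event stage, prediction,
# encounter similarity.  Uses the fast feature-level click fixture; the
# full waveform path is exercised by the acceptance suite.

test_that("stage-1 event features follow the detector-proportion contract", {
  cl <- make_click_table()
  set.seed(1)
  cs <- fit_call_stage(cl, sampsize = 30, ntree = 300)
  ef <- cs$event_features
  ret <- cs$detectors
  expect_gte(length(ret), 2)
  prop_cols <- paste0("prop_d", ret)
  # proportions over retained detectors sum to 1 per event (or 0 if none)
  sums <- rowSums(ef[, prop_cols, drop = FALSE])
  expect_true(all(abs(sums - 1) < 1e-9 | sums == 0))

  # an event with all clicks in one detector: proportion (1, 0, 0, ...)
  ev1 <- cl[cl$event_id == cl$event_id[1], ]
  ev1$detector_code <- ret[1]
  ef1 <- echoclass:::.assemble_event_features(
    ev1, ret, sort(unique(cl$species)), rep(0.8, nrow(ev1)))
  expect_equal(ef1[[paste0("prop_d", ret[1])]], 1)
  for (code in ret[-1]) {
    expect_equal(ef1[[paste0("prop_d", code)]], 0)
    # neutral probability for empty detectors
    expect_equal(ef1[[paste0("pr_beluga_d", code)]], 0.5)
  }

  # species probabilities are complements
  for (code in ret) {
    expect_equal(ef[[paste0("pr_beluga_d", code)]] +
                   ef[[paste0("pr_narwhal_d", code)]],
                 rep(1, nrow(ef)))
  }
})

test_that("detectors with insufficient clicks are dropped", {
  cl <- make_click_table()
  # starve detector 5 for belugas
  cl <- cl[!(cl$species == "beluga" & cl$detector_code == 5), ]
  set.seed(2)
  cs <- fit_call_stage(cl, sampsize = 30, ntree = 100)
  expect_false(5 %in% cs$detectors)
  expect_true(5 %in% cs$dropped)
  expect_error(fit_call_stage(cl[cl$detector_code == 2, ],
                              sampsize = 30, ntree = 50),
               "fewer than two detectors")
})

test_that("perfectly separating stage-1 features give 100% OOB", {
  set.seed(3)
  n <- 40
  ef <- data.frame(
    event_id = sprintf("e%02d", 1:n),
    species = rep(c("beluga", "narwhal"), each = n / 2),
    prop_d2 = runif(n), prop_d3 = runif(n),
    pr_beluga_d2 = rep(c(1, 0), each = n / 2),
    pr_narwhal_d2 = rep(c(0, 1), each = n / 2),
    ici = runif(n, 0.1, 0.2), n_retained_clicks = 50)
  es <- fit_event_stage(ef, sampsize = 9, ntree = 500)
  expect_equal(es$summary$rate_pct[es$summary$class == "Overall"], 100)
  # per-event vote fractions over trees sum to 1
  expect_equal(unname(rowSums(es$vote_fraction)), rep(1, n))
})

test_that("self-prediction is consistent and flags empty events", {
  cl <- make_click_table()
  set.seed(4)
  model <- fit_banter(cl, sampsize1 = 30, ntree1 = 500, ntree2 = 500)
  pred <- predict_events(model, cl)
  expect_equal(nrow(pred), length(unique(cl$event_id)))
  votes <- pred[, grep("^vote_", names(pred))]
  expect_true(all(votes >= 0 & votes <= 1))
  expect_equal(unname(rowSums(votes)), rep(1, nrow(pred)))
  # high-confidence events reproduce their labels
  confident <- pmax(votes[, 1], votes[, 2]) > 0.8
  expect_true(all(pred$predicted[confident] == pred$observed[confident]))

  # an event whose clicks all fall outside retained detectors is flagged
  bad <- cl[cl$event_id == cl$event_id[1], ]
  bad$event_id <- "odd_event"
  bad$detector_code <- 0L
  expect_warning(p2 <- predict_events(model, rbind(cl, bad)),
                 "unclassifiable")
  expect_true(is.na(p2$predicted[p2$event_id == "odd_event"]))
})

test_that("stage-1 probabilities come from OOB votes only", {
  cl <- make_click_table()
  set.seed(5)
  cs <- fit_call_stage(cl, sampsize = 30, ntree = 200)
  m <- cs$models[[1]]
  # every click has at least one OOB vote (sampsize << n) and the
  # vote fractions are proper probabilities
  expect_true(all(rowSums(m$votes) > 0))
  expect_true(all(m$vote_fraction >= 0 & m$vote_fraction <= 1))
  tot <- rowSums(m$votes)
  expect_true(all(tot + m$inbag_count == m$ntree))
})

test_that("encounter similarity builds one model per encounter pair", {
  cl <- make_click_table(n_enc = c(beluga = 2, narwhal = 5),
                         events_per_enc = 5, clicks_per_event = 40)
  set.seed(6)
  res <- encounter_similarity(cl, ntree = 200)
  expect_equal(nrow(res), 10)                 # 2 x 5 encounter design
  expect_true(all(is.finite(res$correlation)))
  expect_true(all(res$correlation >= -1 & res$correlation <= 1))
  expect_identical(res$similar, res$correlation > 0.5)
  conf <- attr(res, "confusions")
  expect_equal(length(conf), 10)
  # identical training and validation confusions correlate to 1
  expect_equal(echoclass:::.confusion_correlation(conf[[1]]$train,
                                                  conf[[1]]$train,
                                                  "cells"), 1)
})

test_that("permuted labels drive the event stage to chance", {
  cl <- make_click_table(events_per_enc = 10, clicks_per_event = 40)
  set.seed(9)
  rates <- vapply(1:5, function(i) {
    cl2 <- cl
    ev <- unique(cl2[, c("event_id", "species")])
    perm <- setNames(sample(ev$species), ev$event_id)
    cl2$species <- unname(perm[cl2$event_id])
    model <- fit_banter(cl2, sampsize1 = 30, ntree1 = 200, ntree2 = 300)
    s <- model$event_stage$summary
    s$rate_pct[s$class == "Overall"]
  }, numeric(1))
  expect_lt(abs(mean(rates) - 50), 12)
})
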