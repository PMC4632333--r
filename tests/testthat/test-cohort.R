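test_that("confusion metrics evaluate the three formulas", {
  expect_equal(confusion_metrics(confusion_counts(3, 2, 0, 0)),
               c(sensitivity = 100, specificity = 100, accuracy = 100))
  expect_equal(confusion_metrics(confusion_counts(0, 0, 1, 1)),
               c(sensitivity = 0, specificity = 0, accuracy = 0))
  expect_equal(confusion_metrics(confusion_counts(1, 1, 1, 1)),
               c(sensitivity = 50, specificity = 50, accuracy = 50))
  # the printed accuracy variant counts TN only
  expect_equal(confusion_metrics(confusion_counts(3, 2, 0, 0),
                                 variant = "printed")[["accuracy"]], 40)
  # undefined metrics are NA, not errors
  m <- confusion_metrics(confusion_counts(0, 5, 0, 0))
  expect_true(is.na(m[["sensitivity"]]))
  expect_equal(m[["specificity"]], 100)
  expect_error(confusion_counts(-1, 0, 0, 0), "nonnegative")
})

test_that("count_confusion maps labels to cells, indeterminate is an error", {
  counts <- count_confusion(c("PD", "PD", "ET", "ET", "PD"),
                            c("PD", "ET", "ET", "PD", "indeterminate"))
  expect_equal(unlist(counts[c("TP", "TN", "FP", "FN")]),
               c(TP = 1, TN = 1, FP = 1, FN = 2))
})

test_that("two_sample_t reproduces a hand-computed pooled-variance test", {
  a <- c(1.1, 2.3, 3.0)
  b <- c(4.0, 5.2, 7.1)
  # closed form: t = (ma - mb) / (sp * sqrt(1/na + 1/nb)), df = na + nb - 2
  sp2 <- (2 * var(a) + 2 * var(b)) / 4
  t_stat <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  p_hand <- 2 * pt(-abs(t_stat), df = 4)
  expect_equal(two_sample_t(a, b), p_hand, tolerance = 1e-10)

  expect_equal(two_sample_t(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_lt(two_sample_t(c(1, 2, 3), c(1, 2, 3) + 100), 1e-6)
  expect_warning(p <- two_sample_t(1, c(2, 3)), ">= 2")
  expect_true(is.na(p))
  expect_warning(p0 <- two_sample_t(c(1, 1), c(2, 2)), "zero pooled variance")
  expect_true(is.na(p0))
})

test_that("two_sample_t p-values are uniform under the null", {
  set.seed(17)
  ps <- replicate(400, two_sample_t(rnorm(20), rnorm(20)))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("separation_distance is min(PD) - max(ET)", {
  expect_equal(separation_distance(c(1, 2), c(-1, -2)), 2)
  expect_equal(separation_distance(0.5, 0.5), 0)
  expect_equal(separation_distance(c(-1, 3), 0), -1)
  expect_error(separation_distance(numeric(0), 1), "nonempty")
})

test_that("delay_sweep produces one row per (lag pair, axis)", {
  cohort <- tiny_cohort(2, 2, seed = 6)
  grid <- list(delay_pair(5, 20), delay_pair(10, 30))
  sw <- delay_sweep(cohort, lag_grid = grid, axes = c("x", "y"))
  expect_equal(nrow(sw), 4)
  expect_equal(sw$d1, c(5, 5, 10, 10))
  expect_equal(sw$axis, c("x", "y", "x", "y"))
  expect_true(all(sw$n_pd == 2 & sw$n_et == 2 & sw$n_excluded == 0))
  # clearly separated classes at the default lags on x
  expect_gt(sw$separation_distance[sw$d1 == 5 & sw$axis == "x"], 0)
  rf_attr <- attr(sw, "rf")
  expect_length(rf_attr, 4)
  expect_length(rf_attr[[1]]$PD, 2)
})

test_that("degenerate sweeps: single subject per group, identical groups", {
  one_each <- tiny_cohort(1, 1, seed = 3)
  sw <- delay_sweep(one_each, lag_grid = list(delay_pair(5, 20)), axes = "x")
  expect_true(is.na(sw$p_value))
  expect_false(is.na(sw$separation_distance))

  # same subjects presented as both groups: overlap and t = 0
  pd <- tiny_cohort(2, 0, seed = 4)
  mirrored <- c(pd, lapply(pd, function(s) {
    s$label <- "ET"; s$subject_id <- paste0("m", s$subject_id); s
  }))
  sw2 <- delay_sweep(mirrored, lag_grid = list(delay_pair(5, 20)), axes = "x")
  expect_lte(sw2$separation_distance, 0)
  expect_equal(sw2$p_value, 1)
})

test_that("subjects with undefined RF are excluded and counted", {
  cohort <- tiny_cohort(1, 1, seed = 8)
  flat <- tremor_recording(rep(0, 1250), rep(0, 1250), rep(0, 1250),
                           task = "resting", subject_id = "flat")
  cohort[[3]] <- list(subject_id = "flat", label = "PD",
                      recordings = list(
                        resting = flat,
                        kinetic = cohort[[1]]$recordings$kinetic))
  expect_message(
    sw <- delay_sweep(cohort, lag_grid = list(delay_pair(5, 20)), axes = "x"),
    "undefined RF")
  expect_equal(sw$n_excluded, 1)
  expect_equal(sw$n_pd, 1)
})

test_that("evaluate_cohort classifies a small clean cohort perfectly", {
  res <- evaluate_cohort(tiny_cohort(3, 3, seed = 10))
  expect_equal(unname(res$metrics), c(100, 100, 100))
  expect_equal(res$counts$TP, 3)
  expect_equal(res$counts$TN, 3)
  expect_true(all(res$table$predicted[res$table$label == "PD"] == "PD"))
})
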