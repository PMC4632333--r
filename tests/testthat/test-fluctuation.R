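test_that("delay_pair validates lag ordering", {
  expect_error(delay_pair(20, 5), "d1 < d2")
  expect_error(delay_pair(0, 5), "positive")
  lp <- delay_pair()
  expect_equal(c(lp$d1, lp$d2), c(5L, 20L))
})

test_that("delay_embed reproduces the difference map point by point", {
  cloud <- delay_embed(c(0, 1, 2, 3, 4, 5), delay_pair(1, 2))
  expect_equal(nrow(cloud$points), 4)
  expect_true(all(cloud$points[, 1] == 1) && all(cloud$points[, 2] == 2))

  const <- delay_embed(rep(7, 50), delay_pair(3, 9))
  expect_true(all(const$points == 0))

  expect_equal(nrow(delay_embed(rnorm(1250), delay_pair(5, 20))$points), 1230)

  # spot-check the definition against direct indexing
  set.seed(8)
  s <- rnorm(100)
  cl <- delay_embed(s, delay_pair(4, 11))
  k <- c(1, 37, 89)
  expect_equal(cl$points[k, 1], s[k + 4] - s[k], ignore_attr = TRUE)
  expect_equal(cl$points[k, 2], s[k + 11] - s[k], ignore_attr = TRUE)

  expect_error(delay_embed(rnorm(20), delay_pair(5, 20)), "exceed")
})

test_that("embedding length contract N - d2 holds over random cases", {
  set.seed(9)
  for (i in 1:25) {
    n <- sample(30:2000, 1)
    d2 <- sample(2:(n - 1), 1)
    d1 <- sample(seq_len(d2 - 1), 1)
    cl <- delay_embed(rnorm(n), delay_pair(d1, d2))
    expect_identical(nrow(cl$points), n - d2)
  }
})

test_that("ellipse area matches the closed form and chi-square coverage", {
  set.seed(10)
  pts <- matrix(rnorm(2e5), ncol = 2)
  ell <- ellipse_summary(pts)
  closed_form <- pi * qchisq(0.95, 2)  # unit covariance: sqrt(det) = 1
  expect_equal(ell$area, closed_form, tolerance = 0.02)
  expect_equal(ell$area,
               pi * qchisq(0.95, 2) * sqrt(det(ell$covariance)))
  # empirical coverage: Mahalanobis distance within the chi-square quantile
  centered <- sweep(pts, 2, ell$center)
  d2 <- rowSums((centered %*% solve(ell$covariance)) * centered)
  expect_equal(mean(d2 <= qchisq(0.95, 2)), 0.95, tolerance = 0.011)
})

test_that("ellipse handles degeneracy and scaling", {
  same <- matrix(1, nrow = 10, ncol = 2)
  ell <- ellipse_summary(same)
  expect_equal(ell$area, 0)
  expect_true(ell$degenerate)
  expect_error(ellipse_summary(matrix(rnorm(4), ncol = 2)), "3 points")

  set.seed(12)
  pts <- matrix(rnorm(2000), ncol = 2) %*% matrix(c(2, 0.5, 0.5, 1), 2)
  a1 <- ellipse_area(pts)
  expect_equal(ellipse_area(3 * pts), 9 * a1)
  expect_equal(ellipse_area(pts, coverage = 0.5),
               a1 * qchisq(0.5, 2) / qchisq(0.95, 2))
})

test_that("temporal_fluctuation is nonnegative, quadratic in amplitude", {
  set.seed(14)
  r <- generate_recording(pd_profile(), "resting", seed = 99)
  tf1 <- temporal_fluctuation(r)
  expect_gt(tf1, 0)

  r2 <- r
  r2$samples <- 2 * r2$samples
  expect_equal(as.numeric(temporal_fluctuation(r2)), 4 * as.numeric(tf1),
               tolerance = 1e-10)

  zeros <- tremor_recording(rep(0, 1250), rep(0, 1250), rep(0, 1250),
                            task = "resting")
  tfz <- temporal_fluctuation(zeros)
  expect_equal(as.numeric(tfz), 0)
  expect_true(attr(tfz, "degenerate"))
})

test_that("a 10x amplitude ratio gives a ~100x TF ratio", {
  hi <- tremor_recording(sinusoid(5, amplitude = 10), rep(0, 1250),
                         rep(0, 1250), task = "resting")
  lo <- tremor_recording(sinusoid(5, amplitude = 1), rep(0, 1250),
                         rep(0, 1250), task = "resting")
  hi$samples[, "y"] <- hi$samples[, "x"]; hi$samples[, "z"] <- hi$samples[, "x"]
  lo$samples[, "y"] <- lo$samples[, "x"]; lo$samples[, "z"] <- lo$samples[, "x"]
  ratio <- as.numeric(temporal_fluctuation(hi)) /
    as.numeric(temporal_fluctuation(lo))
  expect_equal(ratio, 100, tolerance = 1e-8)
})

test_that("fluctuation_ratio implements log10(100 TF_rest / TF_kin)", {
  expect_equal(fluctuation_ratio(0.01 * 7, 7), 0)
  expect_equal(fluctuation_ratio(7, 7), 2)
  expect_equal(fluctuation_ratio(0.7, 7), 1)
  expect_equal(fluctuation_ratio(2, 5, log_base = exp(1)), log(40))
  expect_error(fluctuation_ratio(0, 1), "positive")
  expect_error(fluctuation_ratio(1, -2), "positive")
})

test_that("RF is invariant under joint rescaling and base-invariant at zero", {
  set.seed(15)
  tf_r <- runif(1, 1, 5); tf_k <- runif(1, 1, 5)
  for (c2 in c(1e-4, 0.3, 1, 250)) {
    expect_equal(fluctuation_ratio(c2 * tf_r, c2 * tf_k),
                 fluctuation_ratio(tf_r, tf_k))
  }
  for (b in c(2, exp(1), 10))
    expect_equal(fluctuation_ratio(0.01 * tf_k, tf_k, log_base = b), 0)
})

test_that("classification matches the published testing-group ratios", {
  expect_equal(vapply(c(0.7298, 0.0679, 0.2788), classify_rf, character(1)),
               rep("PD", 3))
  expect_equal(vapply(c(-3.1430, -1.8253), classify_rf, character(1)),
               rep("ET", 2))
  expect_equal(classify_rf(0), "indeterminate")
  expect_error(classify_rf(NaN), "finite")
})

test_that("subject_features assembles TF, RF and the label", {
  subj <- tiny_cohort(1, 0, seed = 2)[[1]]
  sf <- subject_features(subj$recordings)
  expect_named(sf$tf_by_task, c("kinetic", "postural", "resting"))
  expect_equal(sf$rf,
               fluctuation_ratio(sf$tf_by_task[["resting"]],
                                 sf$tf_by_task[["kinetic"]]))
  expect_equal(sf$predicted_label, "PD")

  # missing kinetic task -> RF undefined, indeterminate
  sf2 <- subject_features(subj$recordings["resting"])
  expect_true(is.na(sf2$rf))
  expect_equal(sf2$predicted_label, "indeterminate")

  expect_error(subject_features(list(sitting = subj$recordings$resting)),
               "unknown task")
})
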