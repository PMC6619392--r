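test_that("concordance matches the brute-force pair count", {
  expect_equal(concordance(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1)
  expect_equal(concordance(c(0, 1, 0, 1), rep(0.3, 4)), 0.5)
  expect_equal(concordance(c(0, 1, 0, 1, 1), c(0.2, 0.1, 0.3, 0.5, 0.5)), 4 / 6)

  set.seed(401)
  for (i in 1:20) {
    y <- rbinom(30, 1, 0.4)
    if (sum(y) %in% c(0, 30)) next
    s <- round(rnorm(30), 1) # rounding induces ties
    expect_equal(concordance(y, s), concordance_brute(y, s))
  }
  expect_error(concordance(rep(1, 5), rnorm(5)), "single outcome class")
})

test_that("concordance is a rank statistic", {
  set.seed(402)
  y <- rbinom(200, 1, 0.5)
  s <- rnorm(200)
  c0 <- concordance(y, s)
  expect_equal(concordance(y, exp(s)), c0)
  expect_equal(concordance(y, 3 * s - 10), c0)
})

test_that("concordance agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(403)
  y <- rbinom(500, 1, 0.5)
  s <- rnorm(500) + y
  ref <- as.numeric(pROC::auc(y, s, direction = "<", quiet = TRUE))
  expect_equal(concordance(y, s), ref, tolerance = 1e-12)
})

test_that("the binormal approximation behaves like a normal-theory AUC", {
  gs <- function(m1, m0, v1, v0) {
    structure(list(mean1 = m1, mean0 = m0, var1 = v1, var0 = v0,
                   n1 = 10, n0 = 10), class = "group_stats")
  }
  expect_equal(binormal_auc(gs(2, 2, 1, 1)), 0.5)
  expect_equal(binormal_auc(gs(sqrt(2), 0, 1, 1)), pnorm(1))
  # swapping the classes mirrors the statistic around 0.5
  expect_equal(binormal_auc(gs(1.3, 0.2, 0.8, 1.1)) +
                 binormal_auc(gs(0.2, 1.3, 1.1, 0.8)), 1)
  expect_error(binormal_auc(gs(1, 0, 0, 0)), "zero total variance")

  # exact binormality: formula vs empirical concordance
  set.seed(404)
  y <- rep(c(1, 0), each = 5e4)
  s <- c(rnorm(5e4, mean = 1), rnorm(5e4))
  expect_lt(abs(binormal_auc(group_stats(y, s)) - concordance(y, s)), 0.005)
})

test_that("the analytic AUC change has the taxonomy-predicted sign", {
  set.seed(405)
  coh <- draw_cohort(5e4, single_predictor_model())
  stats_x <- group_stats(coh$y, coh$X[, 1])

  expect_equal(delta_auc(stats_x, identity_spec()), 0)
  expect_lt(delta_auc(stats_x, measurement_spec(err_var = 1)), 0)
  # nondifferential systematic error: no effect beyond the random part
  expect_equal(delta_auc(stats_x, measurement_spec(psi = 0.25)), 0,
               tolerance = 1e-12)
  # cases shifted upwards widens the class separation
  expect_gt(delta_auc(stats_x, measurement_spec(psi0 = 0, psi1 = 0.5)), 0)
})

test_that("Brier score and its decomposition are exact", {
  expect_equal(brier_score(c(1, 0, 1), c(1, 0, 1)), 0)
  expect_equal(brier_score(c(1, 0), c(0.5, 0.5)), 0.25)
  expect_equal(brier_score(c(1, 0), c(0.8, 0.4)), 0.10)
  expect_error(brier_score(c(1, 0), c(1.2, 0.4)), "\\[0, 1\\]")

  parts <- brier_decomposition(c(1, 0), c(0.8, 0.4))
  expect_equal(parts$calibration_term, -0.10)
  expect_equal(parts$refinement_term, 0.20)
  expect_equal(parts$total, 0.10)

  set.seed(406)
  for (i in 1:25) {
    y <- rbinom(50, 1, 0.5)
    p <- runif(50)
    parts <- brier_decomposition(y, p)
    expect_equal(parts$calibration_term + parts$refinement_term,
                 brier_score(y, p), tolerance = 1e-12)
    expect_true(parts$refinement_term >= 0 && parts$refinement_term <= 0.25)
  }
})

test_that("in-sample ML predictions have a near-zero calibration term", {
  set.seed(407)
  coh <- draw_cohort(5e4, single_predictor_model())
  fit <- fit_logistic(coh$y, coh$X)
  parts <- brier_decomposition(coh$y, fit$fitted)
  expect_lt(abs(parts$calibration_term), 1e-3)
})

test_that("the expected Brier change is the refinement difference", {
  p <- runif(20)
  expect_equal(expected_delta_brier(p, p), 0)
  expect_equal(expected_delta_brier(c(0.5, 0.5), c(0.9, 0.1)), 0.16)
  # predictions pulled toward the event rate are less accurate
  set.seed(408)
  p_x <- runif(1000)
  p_w <- 0.5 + 0.5 * (p_x - 0.5)
  expect_gt(expected_delta_brier(p_w, p_x), 0)
})

test_that("recalibration returns (0, 1) in the derivation sample", {
  set.seed(409)
  coh <- draw_cohort(2000, single_predictor_model())
  fit <- fit_logistic(coh$y, coh$X)
  lp <- linear_predictor(fit, coh$X)
  cal <- recalibrate(coh$y, lp)
  expect_equal(cal$slope, 1, tolerance = 1e-6)
  expect_equal(cal$intercept, 0, tolerance = 1e-6)
  expect_equal(calibration_in_the_large(coh$y, lp), 0, tolerance = 1e-6)

  # reparameterization: scaling the linear predictor scales the slope back
  cal2 <- recalibrate(coh$y, 2 * lp)
  expect_equal(cal2$slope, cal$slope / 2, tolerance = 1e-6)
  # shifting the linear predictor shifts the intercept-only offset fit
  expect_equal(calibration_in_the_large(coh$y, lp + 0.7), -0.7,
               tolerance = 1e-6)
  expect_error(recalibrate(coh$y, rep(1, coh$n)), "non-constant")
})

test_that("quantile-binned calibration curves cover the sample", {
  curve <- calibration_curve(c(0, 0, 1, 1), c(0, 0, 1, 1), n_bins = 2)
  expect_equal(curve$mean_pred, c(0, 1))
  expect_equal(curve$obs_frac, c(0, 1))
  expect_equal(sum(curve$n), 4)

  expect_warning(
    curve1 <- calibration_curve(rep(c(0, 1), 10), rep(0.5, 20), n_bins = 4),
    "collapsed"
  )
  expect_equal(nrow(curve1), 1)
  expect_equal(curve1$mean_pred, 0.5)
  expect_equal(curve1$obs_frac, 0.5)
  expect_error(calibration_curve(c(0, 1), c(0.2, 0.8), n_bins = 1), "at least 2")

  set.seed(410)
  p <- runif(2e4)
  y <- rbinom(2e4, 1, p)
  curve2 <- calibration_curve(y, p, n_bins = 10)
  expect_equal(sum(curve2$n), 2e4)
  expect_lt(max(abs(curve2$mean_pred - curve2$obs_frac)), 0.03)
})

test_that("delimited prediction tables round-trip through the metric set", {
  set.seed(411)
  coh <- draw_cohort(500, single_predictor_model())
  fit <- fit_logistic(coh$y, coh$X)
  p <- fit$fitted
  path <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(outcome = coh$y, prediction = p), path,
                   row.names = FALSE)
  res <- evaluate_prediction_table(path, scale = "probability")
  expect_equal(res$c_stat, concordance(coh$y, p))
  expect_equal(res$brier, brier_score(coh$y, p))
  expect_equal(res$slope, 1, tolerance = 1e-5)
  unlink(path)
})
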