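test_that("fit metrics match hand arithmetic", {
  r <- fit_metrics(c(0, 0.5, 1), c(0.1, 0.5, 0.9))
  expect_equal(r$rmse, sqrt(0.02 / 3), tolerance = 1e-12)
  expect_equal(r$mae, 1 / 15, tolerance = 1e-12)
  perfect <- fit_metrics(c(0.2, 0.5, 0.9), c(0.2, 0.5, 0.9))
  expect_equal(perfect$rmse, 0)
  expect_equal(perfect$mae, 0)
  expect_equal(perfect$r2, 1)
  # RMSE dominates |mean error| and MAE for arbitrary inputs
  set.seed(41)
  for (i in 1:10) {
    o <- runif(50); p <- runif(50)
    m <- fit_metrics(o, p)
    expect_gte(m$rmse, abs(mean(o - p)) - 1e-12)
    expect_gte(m$rmse, m$mae - 1e-12)
  }
})

test_that("constant predictions leave correlation R2 undefined", {
  r <- fit_metrics(c(0.1, 0.5, 0.9), c(0.5, 0.5, 0.5))
  expect_true(is.na(r$r2))
  expect_false(is.na(r$r2_sse))
})

test_that("out-of-range percentages count against the unit interval", {
  r <- fit_metrics(rep(0.5, 5), c(-0.1, 0.2, 0.6, 1.1, 1.2))
  expect_equal(r$pct_pred_gt1, 40)
  expect_equal(r$pct_pred_lt0, 20)
})

test_that("prediction bands match brute-force enumeration", {
  o <- c(0.5, 1, 0.4, 0.8)
  p <- c(0.52, 0.9, 0.3, 0.8)
  b <- prediction_bands(o, p)
  # relative errors: 0.04, 0.10, 0.25, 0
  expect_equal(as.vector(b), c(2, 3, 3, 3, 4, 4) / 4)
  expect_true(all(diff(b) >= 0))
  perfect <- prediction_bands(o, o)
  expect_true(all(perfect == 1))
  withzero <- prediction_bands(c(0, o), c(0.1, p))
  expect_equal(attr(withzero, "n_excluded_zero"), 1L)
  expect_equal(as.vector(withzero), as.vector(b))
})

test_that("health-state curves aggregate by state in severity order", {
  states <- c("11111", "21222", "11321", "21222", "33333")
  d <- data.frame(eq5d_state = states,
                  eq5d_utility = unname(tto_value(states)))
  curve <- health_state_curve(d, d$eq5d_utility)
  expect_identical(curve$state, c("11111", "21222", "11321", "33333"))
  expect_equal(curve$n, c(1L, 2L, 1L, 1L))
  # a perfect model reproduces the tariff value at every state
  expect_equal(curve$predicted_mean, curve$utility_tariff)
  expect_equal(curve$observed_mean, curve$utility_tariff)
  one <- health_state_curve(
    data.frame(eq5d_state = rep("21222", 4),
               eq5d_utility = rep(0.62, 4)),
    rep(0.6, 4))
  expect_equal(nrow(one), 1L)
  expect_equal(one$n, 4L)
  expect_error(health_state_curve(data.frame(x = 1), 1), "not found")
})

test_that("linear fits over-predict at poor health states on ceiling data", {
  d <- simulate_trial(trial_preset("soccar"), seed = 42)
  lin <- fit_linear(mapping_formula(), d)
  curve <- health_state_curve(d, lin, cut_state = "22222")
  over <- attr(curve, "overprediction")
  expect_gt(as.numeric(over["mean_error_poor"]),
            as.numeric(over["mean_error_good"]))
  expect_gt(as.numeric(over["mean_error_poor"]), 0)
})

test_that("train-equals-test validation reproduces in-sample metrics", {
  d <- make_zoib_data(500, seed = 43)
  rep <- cross_validate(d, d, "linear", y ~ x)
  fit <- fit_linear(y ~ x, d)
  direct <- fit_metrics(d$y, predict(fit))
  expect_equal(rep$rmse, direct$rmse, tolerance = 1e-12)
  expect_equal(rep$aic, AIC(fit), tolerance = 1e-12)
  # cross-dataset reports refuse AIC
  d2 <- make_zoib_data(300, seed = 44)
  rep2 <- cross_validate(d, d2, "linear", y ~ x)
  expect_true(is.na(rep2$aic))
  expect_error(cross_validate(d, data.frame(z = 1), "linear", y ~ x),
               "schema")
})

test_that("zoib generalizes across simulated trial profiles", {
  train <- simulate_trial(trial_preset("topical"), seed = 45)
  test <- simulate_trial(trial_preset("soccar"), seed = 46)
  t0 <- Sys.time()
  rep <- cross_validate(train, test, "zoib", mapping_formula(),
                        subject = "subject_id")
  expect_lt(as.numeric(difftime(Sys.time(), t0, units = "secs")), 60)
  expect_gt(rep$r2, 0.3)
  expect_equal(rep$predicted_mean, mean(test$eq5d_utility),
               tolerance = 0.15)
})

test_that("coverage collapses to zero for an unreachable target", {
  d0 <- make_zoib_data(300, seed = 47)
  res <- coverage_study(
    simulate_fn = function(i) make_zoib_data(300, seed = 1000 + i),
    fit_fn = function(d) zoib(y ~ x, d),
    target_mean = 0.05, n_replicates = 30)
  expect_equal(res$coverage_pct, 0)
  expect_equal(res$n_used, 30L)
})

test_that("failed replicates are excluded and counted", {
  res <- coverage_study(
    simulate_fn = function(i) {
      if (i %% 3 == 0) stop("bad draw")
      make_zoib_data(200, seed = 2000 + i)
    },
    fit_fn = function(d) zoib(y ~ x, d),
    target_mean = 0.7, n_replicates = 15)
  expect_equal(res$n_failed, 5L)
  expect_equal(res$n_used, 10L)
})
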