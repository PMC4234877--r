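test_that("presets load and validate", {
  for (p in c("topical", "soccar")) {
    cfg <- trial_preset(p)
    expect_setequal(names(cfg$domains), qlq_domains)
    expect_true(cfg$utility$mean > 0 && cfg$utility$mean < 1)
  }
  expect_equal(trial_preset("topical")$n_subjects, 670)
  expect_equal(trial_preset("soccar")$n_obs, 1002)
  bad <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(n_subjects = 10), bad)
  expect_error(trial_preset(bad), "missing fields")
})

test_that("simulated trials match their configured structure", {
  for (p in c("topical", "soccar")) {
    cfg <- trial_preset(p)
    d <- simulate_trial(cfg, seed = 101)
    expect_equal(nrow(d), cfg$n_obs)
    expect_equal(length(unique(d$subject_id)), cfg$n_subjects)
    expect_false(anyDuplicated(d[c("subject_id", "visit")]) > 0)
    expect_true(all(d$visit >= 1 & d$visit <= cfg$max_visits))
    for (v in qlq_domains) {
      expect_true(all(d[[v]] >= 0 & d[[v]] <= 100))
    }
    u <- d$eq5d_utility
    expect_true(all(u >= -0.59 & u <= 1))
    expect_equal(mean(u), cfg$utility$mean, tolerance = 0.03)
    expect_equal(sd(u), cfg$utility$sd, tolerance = 0.03)
    expect_equal(mean(u == 1), cfg$utility$p_one, tolerance = 0.03)
    expect_lt(mean(u < 0), 0.005)
  }
})

test_that("domain-utility correlations track the configured targets", {
  cfg <- trial_preset("topical")
  d <- simulate_trial(cfg, seed = 102)
  r_target <- vapply(cfg$domains[qlq_domains], `[[`, numeric(1), "r")
  r_ach <- cor(d$eq5d_utility, as.matrix(d[qlq_domains]))[1, ]
  expect_true(all(sign(r_ach) == sign(r_target)))
  # truncation to the score range distorts the most skewed domains; the
  # achieved values stay near the targets and inside the configured span
  expect_true(all(abs(r_ach - r_target) < 0.15))
  expect_true(all(abs(r_ach) > 0.2 & abs(r_ach) < 0.8))
  expect_identical(names(which.max(abs(r_ach)))[1], "PF")
})

test_that("seeded simulation is exactly reproducible", {
  cfg <- trial_preset("soccar")
  d1 <- simulate_trial(cfg, seed = 7)
  d2 <- simulate_trial(cfg, seed = 7)
  expect_identical(d1, d2)
  d3 <- simulate_trial(cfg, seed = 8)
  expect_false(identical(d1$eq5d_utility, d3$eq5d_utility))
})

test_that("a near-normal uncorrelated config yields normal-looking marginals", {
  cfg <- trial_preset("topical")
  for (v in names(cfg$domains)) {
    cfg$domains[[v]]$mean <- 50
    cfg$domains[[v]]$sd <- 12
    cfg$domains[[v]]$r <- 0
  }
  d <- simulate_trial(cfg, seed = 103)
  pf <- d$PF
  expect_equal(skewness(pf), 0, tolerance = 0.15)
  expect_equal(exkurtosis(pf), 0, tolerance = 0.35)
  expect_equal(cor(d$eq5d_utility, d$PF), 0, tolerance = 0.08)
})

test_that("exponential survival has the right mean and ordering", {
  set.seed(104)
  s <- simulate_survival(lambda_os = 1, lambda_pfs = 2, n = 1e5)
  expect_equal(mean(s$os), 1, tolerance = 3 / sqrt(1e5))
  expect_equal(mean(s$pfs), 0.5, tolerance = 3 * 0.5 / sqrt(1e5))
  expect_true(all(s$pfs < s$os))
  expect_error(simulate_survival(0, n = 10), "positive")
  expect_error(simulate_survival(2, lambda_pfs = 1, n = 10),
               "must exceed")
})

test_that("administrative censoring clips times and flags events", {
  set.seed(105)
  s <- simulate_survival(lambda_os = 0.5, n = 1000, kappa = 1,
                         censor_time = 2)
  expect_true(all(s$os <= 2))
  expect_true(any(!s$os_event))
  expect_true(all(s$os[!s$os_event] == 2))
})

test_that("the marginal utility sampler hits its targets", {
  set.seed(106)
  u <- simulate_utility_margin(0.75, 0.23, p_one = 0.25, n = 5e4)
  expect_equal(mean(u), 0.75, tolerance = 0.02)
  expect_equal(sd(u), 0.23, tolerance = 0.02)
  expect_equal(mean(u == 1), 0.25, tolerance = 0.02)
  expect_true(all(u >= 0 & u <= 1))
})
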