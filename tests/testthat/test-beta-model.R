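test_that("method of moments inverts the beta mean/variance formulas", {
  s <- moments_to_shapes(0.5, 1 / 12)
  expect_equal(s$alpha, 1, tolerance = 1e-12)
  expect_equal(s$beta, 1, tolerance = 1e-12)
  # round trip through the moment formulas
  for (mu in c(0.2, 0.61, 0.9)) {
    for (v in c(0.01, 0.05)) {
      sh <- moments_to_shapes(mu, v)
      m <- shapes_to_moments(sh$alpha, sh$beta)
      expect_equal(m$mu, mu, tolerance = 1e-12)
      expect_equal(m$sigma2, v, tolerance = 1e-12)
      expect_equal(sh$alpha, sh$mu * sh$phi, tolerance = 1e-12)
    }
  }
  expect_error(moments_to_shapes(0.5, 0.3), "infeasible variance")
  expect_error(moments_to_shapes(1, 0.01), "strictly in")
})

test_that("trial-scale moments give beta shape parameters below one", {
  expect_equal(moments_to_shapes(0.61, 0.29^2)$beta, 0.713, tolerance = 1e-3)
  expect_equal(moments_to_shapes(0.75, 0.23^2)$beta, 0.636, tolerance = 1e-3)
  expect_lt(moments_to_shapes(0.61, 0.29^2)$beta, 1)
  expect_lt(moments_to_shapes(0.75, 0.23^2)$beta, 1)
})

test_that("beta log-density matches the shape-parameter form and normalizes", {
  expect_equal(beta_logdensity(0.3, 0.5, 2), 0, tolerance = 1e-12)
  set.seed(11)
  for (i in 1:20) {
    y <- runif(1, 0.01, 0.99); mu <- runif(1, 0.05, 0.95)
    phi <- exp(runif(1, -1, 3))
    a <- mu * phi; b <- (1 - mu) * phi
    direct <- lgamma(a + b) - lgamma(a) - lgamma(b) +
      (a - 1) * log(y) + (b - 1) * log(1 - y)
    expect_equal(beta_logdensity(y, mu, phi), direct, tolerance = 1e-10)
  }
  quad <- stats::integrate(function(y) exp(beta_logdensity(y, 0.61, 1.8)),
                           0, 1)
  expect_equal(quad$value, 1, tolerance = 1e-6)
  expect_error(beta_logdensity(0, 0.5, 2), "inflation")
})

test_that("link functions are overflow-safe inverses", {
  expect_equal(mean_link(0), 0.5)
  expect_equal(mean_link(1e4), 1)
  expect_equal(mean_link(-1e4), 0)
  for (mu in c(0.1, 0.61, 0.95)) {
    expect_equal(mean_link(mean_link_inv(mu)), mu, tolerance = 1e-12)
  }
  expect_equal(dispersion_link(0), 1)
  expect_equal(dispersion_link(log(2)), 2)
})

test_that("the inflated log-likelihood matches a hand-computed evaluation", {
  y <- c(0, 0.5, 1)
  X <- W <- matrix(1, 3, 1)
  beta <- 0.3; delta <- 0.4; p0 <- 0.2; p1 <- 0.3
  mu <- exp(beta) / (1 + exp(beta)); phi <- exp(delta)
  a <- mu * phi; b <- (1 - mu) * phi
  hand <- log(p0) + log(p1) + log(1 - p0 - p1) +
    (lgamma(a + b) - lgamma(a) - lgamma(b) +
       (a - 1) * log(0.5) + (b - 1) * log(0.5))
  expect_equal(zoib_loglik(y, X, W, beta, delta, p0, p1), hand,
               tolerance = 1e-12)
  # degenerate inflation on interior data reduces to plain beta regression
  y2 <- c(0.2, 0.5, 0.9)
  plain <- sum(beta_logdensity(y2, mu, phi))
  expect_equal(zoib_loglik(y2, X, W, beta, delta, 0, 0), plain,
               tolerance = 1e-12)
  # boundary data with zero mass is impossible
  expect_identical(zoib_loglik(y, X, W, beta, delta, 0, 0), -Inf)
})

test_that("the likelihood peaks near the generating parameters", {
  d <- make_zoib_data(800, seed = 4)
  X <- cbind(1, d$x); W <- matrix(1, nrow(d), 1)
  at_truth <- zoib_loglik(d$y, X, W, c(1.0, 0.02), 1.2, 0.03, 0.12)
  set.seed(5)
  worse <- replicate(10, {
    zoib_loglik(d$y, X, W, c(1.0, 0.02) + rnorm(2, 0, c(0.3, 0.006)),
                1.2 + rnorm(1, 0, 0.3), 0.03, 0.12)
  })
  expect_true(mean(at_truth > worse) >= 0.8)
})

test_that("zoib recovers generating parameters with sensible diagnostics", {
  d <- make_zoib_data(1500, seed = 7)
  fit <- zoib(y ~ x, d)
  expect_true(fit$converged)
  est <- c(fit$coefficients$mean, fit$coefficients$dispersion)
  se <- sqrt(diag(fit$vcov))
  expect_true(all(abs(est - c(1.0, 0.02, 1.2)) < 4 * se))
  expect_true(all(se > 0))
  expect_equal(fit$inflation$p0, mean(d$y == 0), tolerance = 1e-12)
  expect_equal(fit$inflation$p1, mean(d$y == 1), tolerance = 1e-12)
  # AIC identity: 2k - 2 loglik
  expect_equal(AIC(fit), 2 * fit$df - 2 * fit$loglik, tolerance = 1e-10)
})

test_that("an intercept-only fit reproduces method-of-moments shapes", {
  set.seed(8)
  sh <- moments_to_shapes(0.61, 0.29^2)
  d <- data.frame(y = rbeta(4000, sh$alpha, sh$beta))
  fit <- zoib(y ~ 1, d, inflation = "none")
  expect_equal(mean_link(fit$coefficients$mean[[1]]), 0.61,
               tolerance = 0.02)
  expect_equal(exp(fit$coefficients$dispersion[[1]]), sh$phi,
               tolerance = 0.15)
})

test_that("degenerate inputs are rejected", {
  d <- data.frame(y = c(0, 1, 1, 0), x = 1:4)
  expect_error(zoib(y ~ x, d), "strictly inside")
  d2 <- make_zoib_data(100, seed = 2)
  d2$x2 <- d2$x * 2
  expect_error(zoib(y ~ x + x2, d2), "rank-deficient")
  expect_error(zoib(y ~ x, d2, inflation = "none"), "boundary")
})

test_that("predictions stay inside the unit interval in both modes", {
  d <- make_zoib_data(600, seed = 9)
  fit <- zoib(y ~ x, d)
  extreme <- data.frame(x = c(-1e4, 0, 50, 100, 1e4))
  pc <- predict(fit, extreme, type = "conditional")
  pm <- predict(fit, extreme, type = "mixture")
  expect_true(all(pc >= 0 & pc <= 1))
  expect_true(all(pm >= 0 & pm <= 1))
  # all-zero covariates reduce to the intercept through the logit link
  expect_equal(predict(fit, data.frame(x = 0), type = "conditional"),
               mean_link(fit$coefficients$mean[[1]]), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(predict(fit, data.frame(z = 1)))
})

test_that("the mixture mean agrees with Monte-Carlo draws from the fit", {
  d <- make_zoib_data(800, seed = 10)
  fit <- zoib(y ~ x, d)
  pm <- mean(predict(fit, type = "mixture"))
  sims <- simulate(fit, nsim = 30, seed = 123)
  mc <- mean(colMeans(sims))
  expect_equal(pm, mc, tolerance = 0.01)
})

test_that("quantile residuals of a well-specified fit look standard normal", {
  d <- make_zoib_data(1200, seed = 12)
  fit <- zoib(y ~ x, d)
  set.seed(1)
  r <- residuals(fit, type = "quantile")
  expect_equal(mean(r), 0, tolerance = 0.1)
  expect_equal(sd(r), 1, tolerance = 0.1)
})

test_that("cluster-robust and observed-information SEs both work", {
  d <- make_zoib_data(500, seed = 13)
  d$subject_id <- rep(1:100, each = 5)
  fit <- zoib(y ~ x, d, subject = "subject_id")
  vo <- vcov(fit); vr <- vcov(fit, type = "robust")
  expect_true(all(diag(vr) > 0))
  expect_equal(dim(vo), dim(vr))
  s <- summary(fit)
  expect_identical(s$se_type, "robust")
})

test_that("a subject random intercept is recovered by quadrature", {
  set.seed(3)
  ns <- 120; nv <- 4; n <- ns * nv
  subj <- rep(seq_len(ns), each = nv)
  x <- runif(n, 0, 100)
  u <- rep(rnorm(ns, 0, 0.5), each = nv)
  mu <- plogis(0.3 + 0.015 * (x - 50) + u)
  d <- data.frame(subject_id = subj, x = x,
                  y = rbeta(n, mu * 8, (1 - mu) * 8))
  fit <- zoib(y ~ x, d, subject = "subject_id", random_intercept = TRUE,
              inflation = "none")
  expect_gt(fit$sigma_u, 0.3)
  expect_lt(fit$sigma_u, 0.8)
  fixed <- zoib(y ~ x, d, subject = "subject_id", inflation = "none")
  expect_gt(fit$loglik, fixed$loglik)
})

test_that("covariate-dependent inflation is fitted by multinomial logit", {
  set.seed(14)
  n <- 1500
  x <- runif(n, 0, 1)
  p1x <- plogis(-2.5 + 2.5 * x)
  y <- rbeta(n, 0.6 * 4, 0.4 * 4)
  one <- runif(n) < p1x
  y[one] <- 1
  d <- data.frame(x = x, y = y)
  fit <- zoib(y ~ x, d, inflation = ~x)
  expect_identical(fit$inflation$kind, "covariate")
  # fitted boundary probability should rise with x
  p1_fit <- fit$inflation$p1
  expect_gt(cor(p1_fit, x), 0.9)
})
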