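test_that("linear fit recovers a noise-free system exactly", {
  d <- data.frame(x1 = runif(50, 0, 100), x2 = runif(50, 0, 100))
  d$y <- 0.2 + 0.004 * d$x1 - 0.002 * d$x2
  fit <- fit_linear(y ~ x1 + x2, d)
  expect_equal(unname(coef(fit)), c(0.2, 0.004, -0.002), tolerance = 1e-10)
})

test_that("a zero-variance random intercept is estimated near zero", {
  set.seed(21)
  d <- data.frame(subject_id = rep(1:80, each = 4),
                  x = runif(320, 0, 100))
  d$y <- 0.3 + 0.003 * d$x + rnorm(320, 0, 0.1)
  fit <- fit_linear(y ~ x, d, subject = "subject_id",
                    random_intercept = TRUE)
  expect_lt(fit$sigma_u, 0.05)
})

test_that("quadratic model nests and reduces to the linear model", {
  set.seed(22)
  d <- data.frame(PF = runif(300, 0, 100), PA = runif(300, 0, 100))
  d$y <- 0.2 + 0.004 * d$PF - 0.002 * d$PA + rnorm(300, 0, 0.05)
  lin <- fit_linear(y ~ PF + PA, d)
  quad <- fit_quadratic(y ~ PF + PA, d)
  # no squared columns requested -> identical to linear
  none <- fit_quadratic(y ~ PF + PA, d, squared = character(0))
  expect_equal(coef(none), coef(lin), tolerance = 1e-12)
  # generator has no curvature -> squared coefficients near zero
  sq <- coef(quad)[grepl("^sq_", names(coef(quad)))]
  expect_true(all(abs(sq) < 0.15))
  # genuine curvature -> quadratic wins on AIC
  d$y2 <- 0.1 + 0.9 * (d$PF / 100)^2 + rnorm(300, 0, 0.05)
  lin2 <- fit_linear(y2 ~ PF, d)
  quad2 <- fit_quadratic(y2 ~ PF, d, squared = "PF")
  expect_lt(AIC(quad2), AIC(lin2))
})

test_that("tobit reduces to Gaussian ML without censored points", {
  set.seed(23)
  d <- data.frame(x = runif(250, 0, 100))
  d$y <- 0.4 + 0.002 * d$x + rnorm(250, 0, 0.05)  # stays inside (0,1)
  stopifnot(all(d$y > 0 & d$y < 1))
  tob <- fit_tobit(y ~ x, d)
  lin <- fit_linear(y ~ x, d)
  expect_equal(unname(coef(tob)), unname(coef(lin)), tolerance = 1e-4)
  expect_equal(tob$loglik, lin$loglik, tolerance = 1e-4)
})

test_that("tobit log-likelihood matches a symbolic four-point evaluation", {
  d <- data.frame(x = c(10, 40, 70, 95),
                  y = c(0, 0.3, 0.7, 1))
  fit <- fit_tobit(y ~ x, d)
  beta <- coef(fit); sigma <- fit$sigma
  xb <- beta[1] + beta[2] * d$x
  hand <- pnorm((0 - xb[1]) / sigma, log.p = TRUE) +
    dnorm(d$y[2], xb[2], sigma, log = TRUE) +
    dnorm(d$y[3], xb[3], sigma, log = TRUE) +
    pnorm((xb[4] - 1) / sigma, log.p = TRUE)
  expect_equal(fit$loglik, unname(hand), tolerance = 1e-8)
})

test_that("tobit undoes the attenuation bias of naive OLS under censoring", {
  set.seed(24)
  n <- 2000
  d <- data.frame(x = runif(n, 0, 100))
  latent <- 0.5 + 0.008 * d$x + rnorm(n, 0, 0.15)
  d$y <- pmin(pmax(latent, 0), 1)  # heavy upper censoring
  expect_gt(mean(d$y == 1), 0.2)
  tob <- fit_tobit(y ~ x, d)
  ols <- fit_linear(y ~ x, d)
  expect_lt(abs(coef(tob)[2] - 0.008), abs(coef(ols)[2] - 0.008))
  expect_equal(unname(coef(tob)[2]), 0.008, tolerance = 0.15)
  # default predictions are clamped to the limits
  expect_true(all(predict(tob) >= 0 & predict(tob) <= 1))
  expect_gt(max(predict(tob, d, type = "latent")), 1)
})

test_that("tobit agrees with an interval-censored survreg fit", {
  skip_if_not_installed("survival")
  set.seed(25)
  d <- data.frame(x = runif(400, 0, 100))
  d$y <- pmin(pmax(0.2 + 0.008 * d$x + rnorm(400, 0, 0.2), 0), 1)
  tob <- fit_tobit(y ~ x, d)
  sv <- survival::survreg(
    survival::Surv(time = ifelse(d$y <= 0, 0, ifelse(d$y >= 1, 1, d$y)),
                   time2 = ifelse(d$y >= 1, NA,
                                  ifelse(d$y <= 0, 0, d$y)),
                   event = ifelse(d$y <= 0, 2, ifelse(d$y >= 1, 0, 1)),
                   type = "interval") ~ x,
    data = d, dist = "gaussian")
  expect_equal(unname(coef(tob)), unname(coef(sv)), tolerance = 5e-3)
  expect_equal(tob$sigma, sv$scale, tolerance = 5e-3)
})

test_that("intercept-only LAD is the sample median", {
  set.seed(26)
  y <- rbeta(301, 2, 3)  # odd n: unique median
  d <- data.frame(y = y)
  fit <- fit_quantile(y ~ 1, d, boot_se = 0)
  expect_equal(unname(coef(fit)), median(y), tolerance = 1e-6)
})

test_that("the LAD solver matches direct check-loss minimization", {
  set.seed(27)
  d <- data.frame(x = runif(300, 0, 100))
  d$y <- 0.2 + 0.006 * d$x + rnorm(300, 0, 0.15)
  check <- function(b, tau = 0.5) {
    r <- d$y - b[1] - b[2] * d$x
    sum(r * (tau - (r < 0)))
  }
  fit <- fit_quantile(y ~ x, d, boot_se = 0)
  oracle <- optim(c(0.5, 0), check, method = "Nelder-Mead",
                  control = list(maxit = 5000, reltol = 1e-12))
  expect_equal(check(coef(fit)), oracle$value, tolerance = 1e-4)
  # symmetric noise: LAD close to OLS at this n
  ols <- fit_linear(y ~ x, d)
  expect_equal(unname(coef(fit)), unname(coef(ols)), tolerance = 0.05)
})

test_that("higher quantile fits lie above the median fit", {
  set.seed(28)
  d <- data.frame(x = runif(400, 0, 100))
  d$y <- 0.3 + 0.004 * d$x + rnorm(400, 0, 0.1)
  f50 <- fit_quantile(y ~ x, d, tau = 0.5, boot_se = 0)
  f90 <- fit_quantile(y ~ x, d, tau = 0.9, boot_se = 0)
  expect_gt(mean(predict(f90, d) - predict(f50, d)), 0.05)
})

test_that("CLAD equals LAD when no censoring is active", {
  set.seed(29)
  d <- data.frame(x = runif(200, 0, 100))
  d$y <- 0.4 + 0.002 * d$x + rnorm(200, 0, 0.05)
  lad <- fit_quantile(y ~ x, d, boot_se = 0)
  clad <- fit_clad(y ~ x, d, boot_se = 0)
  expect_equal(coef(clad), coef(lad), tolerance = 1e-10)
  expect_true(clad$converged)
})

test_that("CLAD recovers the latent median line under a ceiling", {
  set.seed(30)
  n <- 1500
  d <- data.frame(x = runif(n, 0, 100))
  latent <- 0.5 + 0.008 * d$x + rnorm(n, 0, 0.12)
  d$y <- pmin(latent, 1)  # mass piled at 1
  expect_gt(mean(d$y == 1), 0.2)
  clad <- fit_clad(y ~ x, d, boot_se = 0)
  lad <- fit_quantile(y ~ x, d, boot_se = 0)
  expect_lt(abs(coef(clad)[2] - 0.008), abs(coef(lad)[2] - 0.008))
  expect_true(all(predict(clad) >= 0 & predict(clad) <= 1))
})

test_that("cluster bootstrap produces positive standard errors", {
  set.seed(31)
  d <- data.frame(subject_id = rep(1:60, each = 3),
                  x = runif(180, 0, 100))
  d$y <- pmin(pmax(0.3 + 0.005 * d$x + rnorm(180, 0, 0.15), 0), 1)
  fit <- fit_quantile(y ~ x, d, subject = "subject_id", boot_se = 40)
  expect_true(all(fit$se > 0))
  expect_length(fit$se, 2L)
})

test_that("fit_mapping dispatches on the model kind", {
  d <- make_zoib_data(300, seed = 32)
  expect_s3_class(fit_mapping("linear", y ~ x, d), "mapfit")
  expect_s3_class(fit_mapping("tobit", y ~ x, d), "mapfit")
  expect_s3_class(fit_mapping("quantile", y ~ x, d, boot_se = 0), "mapfit")
  expect_s3_class(fit_mapping("clad", y ~ x, d, boot_se = 0), "mapfit")
  expect_s3_class(fit_mapping("zoib", y ~ x, d), "zoib")
  expect_error(fit_mapping("probit", y ~ x, d))
})
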