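#' Control parameters for [zoib()]
#'
#' @param maxit maximum quasi-Newton iterations.
#' @param reltol relative convergence tolerance on the log-likelihood.
#' @param gh_nodes number of Gauss-Hermite nodes for the random-intercept
#'   integral.
#' @param multistart also start the optimizer from the zero vector and keep
#'   the better of the two solutions.
#' @return A list of control values.
#' @export
zoib_control <- function(maxit = 500L, reltol = 1e-10, gh_nodes = 15L,
                         multistart = TRUE) {
  list(maxit = as.integer(maxit), reltol = reltol,
       gh_nodes = as.integer(gh_nodes), multistart = isTRUE(multistart))
}

# Continuous-part log-likelihood: sum of beta log-densities at
# mu = plogis(X beta), phi = exp(W delta).  Returns -Inf-safe value.
.beta_part_loglik <- function(theta, y, X, W) {
  p <- ncol(X)
  eta <- drop(X %*% theta[seq_len(p)])
  zeta <- drop(W %*% theta[p + seq_len(ncol(W))])
  if (any(abs(zeta) > 50) || any(abs(eta) > 500)) return(-1e10)
  mu <- stats::plogis(eta)
  phi <- exp(zeta)
  ll <- sum(stats::dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE))
  if (!is.finite(ll)) -1e10 else ll
}

# Analytic gradient of .beta_part_loglik.  Standard beta-regression score:
# d l / d eta_i = phi_i (y* - mu*) mu (1 - mu),  y* = logit(y),
# mu* = digamma(mu phi) - digamma((1 - mu) phi);
# d l / d zeta_i = phi_i [digamma(phi) - mu digamma(mu phi)
#                         - (1 - mu) digamma((1 - mu) phi)
#                         + mu log y + (1 - mu) log(1 - y)].
.beta_part_score_obs <- function(theta, y, X, W) {
  p <- ncol(X)
  eta <- drop(X %*% theta[seq_len(p)])
  zeta <- drop(W %*% theta[p + seq_len(ncol(W))])
  mu <- stats::plogis(eta)
  phi <- exp(zeta)
  ystar <- stats::qlogis(y)
  mustar <- digamma(mu * phi) - digamma((1 - mu) * phi)
  d_eta <- phi * (ystar - mustar) * mu * (1 - mu)
  d_zeta <- phi * (digamma(phi) - mu * digamma(mu * phi) -
                     (1 - mu) * digamma((1 - mu) * phi) +
                     mu * log(y) + (1 - mu) * log1p(-y))
  cbind(X * d_eta, W * d_zeta)
}

.beta_part_grad <- function(theta, y, X, W) {
  colSums(.beta_part_score_obs(theta, y, X, W))
}

# Random-intercept continuous-part log-likelihood, integrating a shared
# N(0, sigma_u^2) intercept per subject by Gauss-Hermite quadrature.
.beta_part_loglik_ranef <- function(theta, y, X, W, subject, gh) {
  p <- ncol(X); q <- ncol(W)
  sigma_u <- exp(theta[p + q + 1L])
  eta <- drop(X %*% theta[seq_len(p)])
  zeta <- drop(W %*% theta[p + seq_len(q)])
  if (any(abs(zeta) > 50)) return(-1e10)
  phi <- exp(zeta)
  nodes <- sqrt(2) * gh$x
  logw <- log(gh$w) - 0.5 * log(pi)
  subj <- factor(subject)
  per_subject <- matrix(0, nlevels(subj), length(nodes))
  for (k in seq_along(nodes)) {
    mu_k <- stats::plogis(eta + sigma_u * nodes[k])
    ld <- stats::dbeta(y, mu_k * phi, (1 - mu_k) * phi, log = TRUE)
    if (any(!is.finite(ld))) return(-1e10)
    per_subject[, k] <- rowsum(ld, subj)[, 1L] + logw[k]
  }
  m <- apply(per_subject, 1L, max)
  ll <- sum(m + log(rowSums(exp(per_subject - m))))
  if (!is.finite(ll)) -1e10 else ll
}

#' Log-likelihood of the zero-one-inflated beta regression
#'
#' The observation-level likelihood is `p0` at `y = 0`, `p1` at `y = 1`, and
#' `(1 - p0 - p1) f(y | mu, phi)` for `y` strictly inside (0, 1), with
#' `mu = plogis(X beta)` and `phi = exp(W delta)`.  With `sigma_u > 0` a
#' shared subject-level normal intercept on the mean linear predictor is
#' integrated out by Gauss-Hermite quadrature.
#'
#' @param y response vector in `[0, 1]`.
#' @param X mean-submodel design matrix (with intercept column).
#' @param W dispersion-submodel design matrix.
#' @param beta,delta coefficient vectors for `X` and `W`.
#' @param p0,p1 boundary inflation probabilities (`p0 + p1 < 1`).
#' @param subject optional subject identifiers (needed when `sigma_u > 0`).
#' @param sigma_u random-intercept standard deviation; 0 disables it.
#' @param gh_nodes Gauss-Hermite node count for the random-intercept case.
#' @return The log-likelihood (a scalar).
#' @export
zoib_loglik <- function(y, X, W, beta, delta, p0 = 0, p1 = 0,
                        subject = NULL, sigma_u = 0, gh_nodes = 15L) {
  X <- as.matrix(X); W <- as.matrix(W)
  if (any(y < 0 | y > 1)) stop("responses must lie in [0, 1]")
  if (p0 < 0 || p1 < 0 || p0 + p1 >= 1) stop("need p0, p1 >= 0 and p0 + p1 < 1")
  i0 <- y == 0; i1 <- y == 1; ic <- !(i0 | i1)
  if ((any(i0) && p0 == 0) || (any(i1) && p1 == 0)) return(-Inf)
  ll_inf <- sum(i0) * ifelse(p0 > 0, log(p0), 0) +
    sum(i1) * ifelse(p1 > 0, log(p1), 0) +
    sum(ic) * log1p(-(p0 + p1))
  theta <- c(beta, delta)
  if (sigma_u > 0) {
    if (is.null(subject)) stop("subject ids are required when sigma_u > 0")
    gh <- pracma::gaussHermite(gh_nodes)
    ll_cont <- .beta_part_loglik_ranef(c(theta, log(sigma_u)), y[ic],
                                       X[ic, , drop = FALSE],
                                       W[ic, , drop = FALSE],
                                       subject[ic], gh)
  } else {
    ll_cont <- .beta_part_loglik(theta, y[ic], X[ic, , drop = FALSE],
                                 W[ic, , drop = FALSE])
  }
  ll_inf + ll_cont
}

#' Zero-one-inflated beta regression for bounded utilities
#'
#' Fits the mapping model at the core of the package: EQ-5D-3L utilities in
#' `[0, 1]` regressed on QLQ-C30 domain scores through a beta likelihood
#' with a logit mean submodel `logit(mu) = X beta` and a log dispersion
#' submodel `phi = exp(W delta)`, with point masses `p0` and `p1` at the
#' boundaries (zero-one inflation).  Estimation is by maximum likelihood:
#' the inflation component is likelihood-separable from the beta component,
#' so boundary membership is fitted as a multinomial (closed-form constant
#' probabilities by default, multinomial logit when `inflation` has
#' covariates) and the beta component by quasi-Newton with analytic
#' gradients, started from an OLS fit on the logit of the
#' boundary-shrunk response and (optionally) from the zero vector.
#'
#' Negative responses are floored at 0 before fitting (the count is kept in
#' the fit); values exactly 0 or 1 are routed to the inflation components.
#'
#' @param formula mean-submodel formula, e.g. `eq5d_utility ~ PF + PA + QL`.
#' @param data a data frame (e.g. a trial dataset from [read_trial_data()]
#'   or [simulate_trial()]).
#' @param dispersion right-hand-side formula for the dispersion submodel;
#'   default intercept-only (a single common precision).
#' @param inflation right-hand-side formula for the boundary-inflation
#'   submodel; default `~ 1` (constant `p0`, `p1`).  Use `"none"` to forbid
#'   inflation (only valid when no boundary observations are present).
#' @param subject optional name of the subject-id column; enables
#'   cluster-robust standard errors and the random intercept.
#' @param random_intercept if `TRUE`, a subject-level normal random
#'   intercept on the mean linear predictor is integrated out by
#'   Gauss-Hermite quadrature.  Default `FALSE`, in which case standard
#'   errors are cluster-robust whenever `subject` is given.
#' @param control see [zoib_control()].
#' @return An object of class `"zoib"` with coefficients, standard errors,
#'   covariance matrix, inflation estimates, log-likelihood, AIC and
#'   convergence information.  Supported methods: `print`, `summary`,
#'   `coef`, `vcov`, `logLik`, `predict`, `fitted`, `residuals`,
#'   `simulate`, `plot`.
#' @examples
#' set.seed(1)
#' d <- data.frame(x = runif(300))
#' eta <- -0.3 + 1.2 * d$x
#' d$y <- rbeta(300, plogis(eta) * 5, (1 - plogis(eta)) * 5)
#' d$y[1:20] <- 1  # ceiling effect
#' fit <- zoib(y ~ x, d)
#' coef(fit)
#' @export
zoib <- function(formula, data, dispersion = ~1, inflation = ~1,
                 subject = NULL, random_intercept = FALSE,
                 control = zoib_control()) {
  cl <- match.call()
  mf <- stats::model.frame(formula, data, na.action = stats::na.omit)
  keep <- as.integer(rownames(mf))
  y <- stats::model.response(mf)
  X <- stats::model.matrix(stats::terms(mf), mf)
  if (qr(X)$rank < ncol(X)) stop("mean design matrix is rank-deficient")
  if (!"(Intercept)" %in% colnames(X)) stop("mean submodel needs an intercept")
  W <- stats::model.matrix(dispersion, data[keep, , drop = FALSE])
  yf <- floor_negative(y)
  n_floored <- attr(yf, "n_floored")
  y <- as.numeric(yf)
  subj <- if (!is.null(subject)) data[[subject]][keep] else NULL
  if (random_intercept && is.null(subj)) {
    stop("random_intercept = TRUE requires a 'subject' column name")
  }

  i0 <- y == 0; i1 <- y == 1; ic <- !(i0 | i1)
  n <- length(y); n0 <- sum(i0); n1 <- sum(i1); nc <- sum(ic)
  if (nc == 0L) {
    stop("no observations strictly inside (0, 1): the beta component ",
         "cannot be estimated")
  }
  no_inflation <- identical(inflation, "none")
  if (no_inflation && (n0 + n1) > 0L) {
    stop("boundary observations present but inflation = \"none\"")
  }

  ## ---- inflation component (separable from the beta component) ----
  infl <- .fit_inflation(y, i0, i1, ic, inflation, data[keep, , drop = FALSE],
                         no_inflation)

  ## ---- beta component on the continuous observations ----
  yc <- y[ic]
  Xc <- X[ic, , drop = FALSE]
  Wc <- W[ic, , drop = FALSE]
  sx <- apply(Xc, 2L, stats::sd); sx[sx == 0 | !is.finite(sx)] <- 1
  sw <- apply(Wc, 2L, stats::sd); sw[sw == 0 | !is.finite(sw)] <- 1
  Xs <- sweep(Xc, 2L, sx, "/")
  Ws <- sweep(Wc, 2L, sw, "/")
  p <- ncol(X); q <- ncol(W)

  # start (i): OLS on logit of the boundary-shrunk response
  y_shrunk <- (yc * (nc - 1) + 0.5) / nc
  z <- stats::qlogis(y_shrunk)
  beta0 <- tryCatch(stats::lm.fit(Xs, z)$coefficients,
                    error = function(e) rep(0, p))
  beta0[!is.finite(beta0)] <- 0
  mu0 <- mean(y_shrunk); v0 <- stats::var(y_shrunk)
  phi0 <- max(mu0 * (1 - mu0) / v0 - 1, 0.5)
  delta0 <- c(log(phi0) * sw[1L], rep(0, q - 1L))
  starts <- list(c(beta0, delta0))
  if (control$multistart) starts <- c(starts, list(rep(0, p + q)))

  if (random_intercept) {
    gh <- pracma::gaussHermite(control$gh_nodes)
    subj_c <- subj[ic]
    negll <- function(th) -.beta_part_loglik_ranef(th, yc, Xs, Ws, subj_c, gh)
    starts <- lapply(starts, function(s) c(s, log(0.25)))
    gradfun <- NULL
  } else {
    negll <- function(th) -.beta_part_loglik(th, yc, Xs, Ws)
    gradfun <- function(th) -.beta_part_grad(th, yc, Xs, Ws)
  }
  fits <- lapply(starts, function(s) {
    tryCatch(
      stats::optim(s, negll, gr = gradfun, method = "BFGS", hessian = FALSE,
                   control = list(maxit = control$maxit,
                                  reltol = control$reltol)),
      error = function(e) list(value = Inf, convergence = 99L))
  })
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  if (!is.finite(best$value)) stop("beta-component optimization failed")
  hess <- stats::optimHess(best$par, negll, gr = gradfun)
  theta_s <- best$par
  converged <- best$convergence == 0L

  # back-transform from the column-scaled basis
  scale_vec <- c(sx, sw, if (random_intercept) 1)
  theta <- theta_s / scale_vec
  Vs <- tryCatch(solve(hess), error = function(e) {
    warning("observed information is singular; standard errors unavailable")
    matrix(NA_real_, length(theta_s), length(theta_s))
  })
  V <- diag(1 / scale_vec) %*% Vs %*% diag(1 / scale_vec)
  par_names <- c(colnames(X), paste0("disp_", colnames(W)),
                 if (random_intercept) "log_sigma_u")
  names(theta) <- par_names
  dimnames(V) <- list(par_names, par_names)

  beta_hat <- theta[seq_len(p)]
  delta_hat <- theta[p + seq_len(q)]
  sigma_u <- if (random_intercept) exp(theta[p + q + 1L]) else 0

  ll_cont <- -best$value
  ll <- ll_cont + infl$loglik
  k <- p + q + infl$n_par + as.integer(random_intercept)

  fit <- structure(list(
    call = cl, formula = formula, dispersion = dispersion,
    inflation = infl, subject = subject,
    coefficients = list(mean = beta_hat, dispersion = delta_hat),
    sigma_u = unname(sigma_u), random_intercept = random_intercept,
    vcov = V, terms = stats::terms(mf),
    loglik = ll, loglik_cont = ll_cont, df = k, nobs = n,
    n_boundary = c(zero = n0, one = n1), n_floored = n_floored,
    y = y, X = X, W = W, subj = subj,
    scale = list(x = sx, w = sw), converged = converged,
    optim = best[c("convergence", "counts")]
  ), class = "zoib")
  fit$fitted <- predict(fit, type = "conditional")
  fit
}

# Inflation component: constant probabilities in closed form, or a
# multinomial-logit submodel via nnet::multinom when covariates are given.
.fit_inflation <- function(y, i0, i1, ic, inflation, data, no_inflation) {
  n <- length(y); n0 <- sum(i0); n1 <- sum(i1)
  if (no_inflation) {
    return(list(kind = "none", p0 = 0, p1 = 0, n_par = 0L, loglik = 0,
                vcov = matrix(0, 2, 2, dimnames = list(c("p0", "p1"),
                                                       c("p0", "p1")))))
  }
  constant <- identical(stats::terms(inflation), stats::terms(~1)) ||
    length(attr(stats::terms(inflation), "term.labels")) == 0L
  if (constant) {
    p0 <- n0 / n; p1 <- n1 / n
    ll <- sum(ifelse(n0 > 0, n0 * log(p0), 0),
              ifelse(n1 > 0, n1 * log(p1), 0),
              sum(ic) * log1p(-(p0 + p1)))
    # multinomial covariance of the boundary-probability estimates
    vc <- rbind(c(p0 * (1 - p0), -p0 * p1),
                c(-p0 * p1, p1 * (1 - p1))) / n
    dimnames(vc) <- list(c("p0", "p1"), c("p0", "p1"))
    list(kind = "constant", p0 = p0, p1 = p1,
         n_par = as.integer(n0 > 0) + as.integer(n1 > 0),
         loglik = ll, vcov = vc)
  } else {
    data$.boundary_cat <- factor(
      ifelse(i0, "zero", ifelse(i1, "one", "cont")),
      levels = c("cont", "zero", "one"))
    data$.boundary_cat <- droplevels(data$.boundary_cat)
    mfit <- nnet::multinom(stats::update(inflation, .boundary_cat ~ .),
                           data = data, trace = FALSE)
    pr <- stats::fitted(mfit)
    if (is.null(dim(pr)) || ncol(pr) == 1L) {
      # two-category case: fitted() is P(second level)
      pr <- cbind(1 - as.vector(pr), as.vector(pr))
      colnames(pr) <- mfit$lev
    }
    p0i <- if ("zero" %in% colnames(pr)) pr[, "zero"] else rep(0, n)
    p1i <- if ("one" %in% colnames(pr)) pr[, "one"] else rep(0, n)
    ll <- sum(log(ifelse(i0, p0i, ifelse(i1, p1i, 1 - p0i - p1i))))
    list(kind = "covariate", model = mfit, p0 = p0i, p1 = p1i,
         n_par = length(stats::coef(mfit)), loglik = ll,
         formula = inflation)
  }
}

#' @export
print.zoib <- function(x, ...) {
  cat("Zero-one-inflated beta regression\n")
  cat("Call: "); print(x$call)
  cat("\nMean coefficients (logit link):\n")
  print(signif(x$coefficients$mean, 4))
  cat("\nDispersion coefficients (log link):\n")
  print(signif(x$coefficients$dispersion, 4))
  if (x$inflation$kind == "constant") {
    cat(sprintf("\nInflation: p0 = %.4f, p1 = %.4f\n",
                x$inflation$p0, x$inflation$p1))
  } else if (x$inflation$kind == "covariate") {
    cat("\nInflation: multinomial-logit submodel (",
        deparse(x$inflation$formula), ")\n", sep = "")
  }
  if (x$random_intercept) {
    cat(sprintf("Random intercept SD: %.4f\n", x$sigma_u))
  }
  cat(sprintf("\nlogLik %.2f   AIC %.2f   n = %d (%d at 0, %d at 1)\n",
              x$loglik, AIC(x), x$nobs, x$n_boundary["zero"],
              x$n_boundary["one"]))
  if (!x$converged) cat("WARNING: optimizer did not report convergence\n")
  invisible(x)
}

#' @export
coef.zoib <- function(object, ...) {
  c(object$coefficients$mean,
    stats::setNames(object$coefficients$dispersion,
                    paste0("disp_", names(object$coefficients$dispersion))))
}

#' @export
vcov.zoib <- function(object, type = c("observed", "robust"), ...) {
  type <- match.arg(type)
  if (type == "observed") return(object$vcov)
  if (is.null(object$subj)) stop("robust vcov needs a subject column")
  if (object$random_intercept) {
    stop("robust vcov is for the fixed-effects fit; the random-intercept ",
         "fit uses the observed information")
  }
  ic <- object$y > 0 & object$y < 1
  theta <- c(object$coefficients$mean, object$coefficients$dispersion)
  sc <- .beta_part_score_obs(theta, object$y[ic],
                             object$X[ic, , drop = FALSE],
                             object$W[ic, , drop = FALSE])
  G <- rowsum(sc, object$subj[ic])
  meat <- crossprod(as.matrix(G))
  V <- object$vcov
  V %*% meat %*% V
}

#' @export
logLik.zoib <- function(object, ...) {
  structure(object$loglik, df = object$df, nobs = object$nobs,
            class = "logLik")
}

#' @export
nobs.zoib <- function(object, ...) object$nobs

#' Predict utilities from a fitted zero-one-inflated beta regression
#'
#' @param object a [zoib()] fit.
#' @param newdata optional data frame of covariates; defaults to the
#'   fitting data.
#' @param type `"conditional"` (default) returns the conditional beta mean
#'   `mu = plogis(X beta)`, always strictly inside (0, 1); `"mixture"`
#'   returns the full mixture mean `p1 + (1 - p0 - p1) mu` (the model's
#'   expected utility including the boundary masses); `"link"` the mean
#'   linear predictor; `"precision"` the fitted precision `phi`.
#' @param ... unused.
#' @return Numeric vector of predictions; always within `[0, 1]` for the
#'   two mean types.
#' @export
predict.zoib <- function(object, newdata = NULL,
                         type = c("conditional", "mixture", "link",
                                  "precision"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    X <- object$X; W <- object$W
  } else {
    tt <- stats::delete.response(object$terms)
    X <- stats::model.matrix(tt, stats::model.frame(tt, newdata,
                                                    na.action = stats::na.pass))
    W <- stats::model.matrix(object$dispersion, newdata)
  }
  if (ncol(X) != length(object$coefficients$mean)) {
    stop("newdata is not conformable with the fitted mean design")
  }
  eta <- drop(X %*% object$coefficients$mean)
  if (type == "link") return(eta)
  if (type == "precision") {
    return(dispersion_link(drop(W %*% object$coefficients$dispersion)))
  }
  mu <- mean_link(eta)
  if (type == "conditional") return(mu)
  if (object$inflation$kind == "covariate" && !is.null(newdata)) {
    stop("mixture predictions on new data require constant inflation")
  }
  p0 <- object$inflation$p0; p1 <- object$inflation$p1
  p1 + (1 - p0 - p1) * mu
}

#' @export
fitted.zoib <- function(object, ...) object$fitted

#' @export
residuals.zoib <- function(object,
                           type = c("response", "quantile"), ...) {
  type <- match.arg(type)
  if (type == "response") return(object$y - object$fitted)
  # randomized quantile residuals: boundary masses spread uniformly
  mu <- object$fitted
  phi <- predict(object, type = "precision")
  p0 <- object$inflation$p0; p1 <- object$inflation$p1
  if (length(p0) == 1L) p0 <- rep(p0, object$nobs)
  if (length(p1) == 1L) p1 <- rep(p1, object$nobs)
  y <- object$y
  u <- numeric(length(y))
  i0 <- y == 0; i1 <- y == 1; ic <- !(i0 | i1)
  u[i0] <- stats::runif(sum(i0), 0, p0[i0])
  u[i1] <- stats::runif(sum(i1), 1 - p1[i1], 1)
  u[ic] <- p0[ic] + (1 - p0[ic] - p1[ic]) *
    stats::pbeta(y[ic], mu[ic] * phi[ic], (1 - mu[ic]) * phi[ic])
  stats::qnorm(pmin(pmax(u, 1e-12), 1 - 1e-12))
}

#' Simulate responses from a fitted zero-one-inflated beta regression
#'
#' Draws each observation from the fitted mixture: boundary 0 with
#' probability `p0`, boundary 1 with probability `p1`, otherwise a
#' Beta(mu phi, (1 - mu) phi) variate.
#'
#' @param object a [zoib()] fit with constant inflation.
#' @param nsim number of simulated response vectors.
#' @param seed optional seed, handled as in [stats::simulate()].
#' @param newdata optional covariate data frame.
#' @param ... unused.
#' @return A data frame with `nsim` columns.
#' @export
simulate.zoib <- function(object, nsim = 1, seed = NULL, newdata = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- predict(object, newdata = newdata, type = "conditional")
  phi <- predict(object, newdata = newdata, type = "precision")
  p0 <- object$inflation$p0; p1 <- object$inflation$p1
  if (length(p0) > 1L) stop("simulate() requires constant inflation")
  n <- length(mu)
  out <- replicate(nsim, {
    cat3 <- stats::runif(n)
    y <- stats::rbeta(n, mu * phi, (1 - mu) * phi)
    y[cat3 < p0] <- 0
    y[cat3 >= p0 & cat3 < p0 + p1] <- 1
    y
  })
  as.data.frame(out, col.names = paste0("sim_", seq_len(nsim)))
}

#' @export
summary.zoib <- function(object, se = c("auto", "observed", "robust"), ...) {
  se <- match.arg(se)
  if (se == "auto") {
    se <- if (!is.null(object$subj) && !object$random_intercept)
      "robust" else "observed"
  }
  V <- vcov(object, type = se)
  ses <- sqrt(pmax(diag(V), 0))
  est <- c(object$coefficients$mean, object$coefficients$dispersion,
           if (object$random_intercept) log(object$sigma_u))
  tab <- cbind(Estimate = est, `Std. Error` = ses,
               `z value` = est / ses,
               `Pr(>|z|)` = 2 * stats::pnorm(-abs(est / ses)))
  rownames(tab) <- rownames(V)
  structure(list(fit = object, coefficients = tab, se_type = se),
            class = "summary.zoib")
}

#' @export
print.summary.zoib <- function(x, ...) {
  cat("Zero-one-inflated beta regression\n")
  cat("Call: "); print(x$fit$call)
  cat("\nCoefficients (", x$se_type, " standard errors):\n", sep = "")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  if (x$fit$inflation$kind == "constant") {
    cat(sprintf("\nInflation: p0 = %.4f, p1 = %.4f\n",
                x$fit$inflation$p0, x$fit$inflation$p1))
  }
  cat(sprintf("logLik %.2f   AIC %.2f   n = %d\n", x$fit$loglik,
              AIC(x$fit), x$fit$nobs))
  invisible(x)
}

#' @export
plot.zoib <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  graphics::plot(x$fitted, x$y, xlab = "Fitted conditional mean",
                 ylab = "Observed utility", main = "Observed vs fitted",
                 pch = 16, cex = 0.5, col = "#00000060")
  graphics::abline(0, 1, col = 2)
  r <- residuals(x, type = "quantile")
  stats::qqnorm(r, main = "Quantile residuals", pch = 16, cex = 0.5,
                col = "#00000060")
  stats::qqline(r, col = 2)
  invisible(x)
}

# Influence-function standard error of the mean mixture prediction
# (the estimator behind "predicted mean" coverage): for
# m-hat = mean_i [p1 + (1 - p0 - p1) mu_i], the estimating-equation
# expansion gives per-observation contributions
#   d_i = (g_i - m-hat) + n A' V s_i
# with A the mean gradient of g_i in all parameters, V the parameter
# covariance and s_i the observation scores.  Clustered by subject when
# subject ids are present.  Constant inflation only.
.mixture_mean_se <- function(object) {
  if (object$inflation$kind == "covariate") {
    stop("mixture-mean SE requires constant inflation")
  }
  y <- object$y; X <- object$X; W <- object$W
  n <- length(y)
  mu <- predict(object, type = "conditional")
  p0 <- object$inflation$p0; p1 <- object$inflation$p1
  g <- p1 + (1 - p0 - p1) * mu
  m_hat <- mean(g)

  theta <- c(object$coefficients$mean, object$coefficients$dispersion)
  p <- length(object$coefficients$mean)
  q <- length(object$coefficients$dispersion)

  ic <- y > 0 & y < 1
  s_bd <- matrix(0, n, p + q)
  s_bd[ic, ] <- .beta_part_score_obs(theta, y[ic], X[ic, , drop = FALSE],
                                     W[ic, , drop = FALSE])
  # scores of (p0, p1) under the constant multinomial component
  s_p <- matrix(0, n, 2L)
  pc <- 1 - p0 - p1
  if (p0 > 0) s_p[, 1L] <- (y == 0) / p0 - ic / pc
  if (p1 > 0) s_p[, 2L] <- (y == 1) / p1 - ic / pc
  s_all <- cbind(s_bd, s_p)

  A_bd <- c(colMeans(X * ((1 - p0 - p1) * mu * (1 - mu))), rep(0, q))
  A_p <- c(mean(-mu), mean(1 - mu))
  A <- c(A_bd, A_p)

  V_bd <- object$vcov[seq_len(p + q), seq_len(p + q), drop = FALSE]
  V <- matrix(0, p + q + 2L, p + q + 2L)
  V[seq_len(p + q), seq_len(p + q)] <- V_bd
  V[p + q + 1:2, p + q + 1:2] <- object$inflation$vcov

  d <- (g - m_hat) + n * drop(s_all %*% (V %*% A))
  if (!is.null(object$subj)) {
    d <- rowsum(d, object$subj)[, 1L]
  }
  se <- sqrt(sum(d^2)) / n
  list(estimate = m_hat, se = se,
       ci = m_hat + c(-1, 1) * stats::qnorm(0.975) * se)
}

#' Predicted mean utility with a model-based confidence interval
#'
#' The mean of the mixture-mean predictions over the fitting sample, with
#' an influence-function standard error that propagates the sampling
#' variability of the coefficient and inflation estimates as well as the
#' covariate sample (clustered by subject when subject ids are present).
#' This is the confidence interval whose Monte-Carlo coverage
#' [coverage_study()] assesses.
#'
#' @param object a [zoib()] fit with constant inflation.
#' @return A list with `estimate`, `se` and the 95% `ci`.
#' @export
predicted_mean_ci <- function(object) {
  stopifnot(inherits(object, "zoib"))
  .mixture_mean_se(object)
}
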