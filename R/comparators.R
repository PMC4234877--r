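#' @title Benchmark mapping estimators
#' @description
#' Five estimators commonly used for utility mapping, sharing one
#' fit/predict contract with [zoib()]: linear (optionally with a subject
#' random intercept), quadratic (squared terms for selected domains),
#' two-limit tobit, quantile/LAD regression, and censored least absolute
#' deviation (CLAD).  All return objects of class `"mapfit"` supporting
#' `predict`, `coef`, `print`, `logLik` and `AIC`.
#' @name comparators
NULL

.mapfit <- function(kind, coefficients, se, loglik, df, nobs, fitted,
                    terms, converged = TRUE, ...) {
  structure(list(model_kind = kind, coefficients = coefficients, se = se,
                 loglik = loglik, df = df, nobs = nobs, fitted = fitted,
                 terms = terms, converged = converged, ...),
            class = "mapfit")
}

.design <- function(formula, data) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.omit)
  X <- stats::model.matrix(stats::terms(mf), mf)
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank-deficient")
  list(y = stats::model.response(mf), X = X, terms = stats::terms(mf),
       keep = as.integer(rownames(mf)))
}

#' Linear (mixed) mapping model
#'
#' Gaussian regression of utility on domain scores, by maximum likelihood.
#' With `random_intercept = TRUE` a subject-level random intercept is
#' integrated analytically via [lme4::lmer()] (ML, not REML); predictions
#' are population-level (fixed effects only), and may fall outside
#' `[0, 1]` - the validation layer counts such values.
#'
#' @param formula model formula, e.g. `eq5d_utility ~ PF + PA`.
#' @param data a data frame.
#' @param subject subject-id column name (required for the random
#'   intercept).
#' @param random_intercept logical.
#' @return A `"mapfit"` object.
#' @export
fit_linear <- function(formula, data, subject = NULL,
                       random_intercept = FALSE) {
  d <- .design(formula, data)
  if (random_intercept) {
    if (is.null(subject)) stop("random_intercept requires 'subject'")
    f2 <- stats::as.formula(
      paste(deparse(formula[[2]]), "~",
            paste(deparse(formula[[3]], width.cutoff = 500), collapse = ""),
            "+ (1 |", subject, ")"))
    m <- lme4::lmer(f2, data = data, REML = FALSE)
    beta <- lme4::fixef(m)
    vc <- as.data.frame(lme4::VarCorr(m))
    sigma_u <- vc$sdcor[vc$grp == subject][1]
    fit <- .mapfit("linear", beta, sqrt(diag(as.matrix(stats::vcov(m)))),
                   as.numeric(stats::logLik(m)),
                   attr(stats::logLik(m), "df"), stats::nobs(m),
                   drop(d$X %*% beta), d$terms,
                   sigma_u = sigma_u, lmer_fit = m)
  } else {
    m <- stats::lm(formula, data = data)
    fit <- .mapfit("linear", stats::coef(m),
                   sqrt(diag(stats::vcov(m))),
                   as.numeric(stats::logLik(m)),
                   attr(stats::logLik(m), "df"), stats::nobs(m),
                   stats::fitted(m), d$terms, sigma = stats::sigma(m))
  }
  fit
}

#' Quadratic mapping model
#'
#' The linear model augmented with squared terms for selected domains
#' (default PF, EF, SF, SL, DI).  Scores are divided by 100 before
#' squaring to keep the design well-conditioned; the scaling is recorded
#' in the fit and applied automatically at prediction time.
#'
#' @inheritParams fit_linear
#' @param squared character vector of domain columns to square.
#' @return A `"mapfit"` object with `model_kind = "quadratic"`.
#' @export
fit_quadratic <- function(formula, data, squared = c("PF", "EF", "SF",
                                                     "SL", "DI"),
                          subject = NULL, random_intercept = FALSE) {
  squared <- intersect(squared, names(data))
  data2 <- .augment_squares(data, squared)
  f2 <- if (length(squared)) {
    stats::update(formula,
                  paste("~ . +", paste0("sq_", squared, collapse = " + ")))
  } else formula
  fit <- fit_linear(f2, data2, subject = subject,
                    random_intercept = random_intercept)
  fit$model_kind <- "quadratic"
  fit$squared <- squared
  fit
}

.augment_squares <- function(data, squared) {
  for (v in squared) data[[paste0("sq_", v)]] <- (data[[v]] / 100)^2
  data
}

# Two-limit censored-normal log-likelihood: point-mass normal-CDF terms at
# the limits, density terms between.
.tobit_negll <- function(par, y, X, lo, hi) {
  p <- ncol(X)
  beta <- par[seq_len(p)]
  sigma <- exp(par[p + 1L])
  xb <- drop(X %*% beta)
  ll <- numeric(length(y))
  at_lo <- y <= lo; at_hi <- y >= hi; mid <- !(at_lo | at_hi)
  ll[at_lo] <- stats::pnorm((lo - xb[at_lo]) / sigma, log.p = TRUE)
  ll[at_hi] <- stats::pnorm((xb[at_hi] - hi) / sigma, log.p = TRUE)
  ll[mid] <- stats::dnorm(y[mid], xb[mid], sigma, log = TRUE)
  v <- -sum(ll)
  if (!is.finite(v)) 1e10 else v
}

#' Two-limit tobit mapping model
#'
#' Censored-normal maximum likelihood with censoring at both response
#' limits (default 0 and 1): observations at the limits contribute normal
#' tail probabilities, interior observations the normal density.  Default
#' predictions are the latent mean clamped to the limits, so no prediction
#' falls outside the valid range; the latent mean is available via
#' `predict(..., type = "latent")`.  An optional subject-level random
#' intercept is integrated by Gauss-Hermite quadrature.
#'
#' @inheritParams fit_linear
#' @param limits lower and upper censoring limits.
#' @param gh_nodes Gauss-Hermite node count for the random intercept.
#' @return A `"mapfit"` object with `model_kind = "tobit"`.
#' @export
fit_tobit <- function(formula, data, limits = c(0, 1), subject = NULL,
                      random_intercept = FALSE, gh_nodes = 15L) {
  d <- .design(formula, data)
  y <- d$y; X <- d$X
  lo <- limits[1L]; hi <- limits[2L]
  if (all(y <= lo | y >= hi)) stop("all observations are censored")
  ols <- stats::lm.fit(X, y)
  start <- c(ols$coefficients, log(max(stats::sd(ols$residuals), 1e-3)))
  p <- ncol(X)
  if (random_intercept) {
    if (is.null(subject)) stop("random_intercept requires 'subject'")
    subj <- factor(data[[subject]][d$keep])
    gh <- pracma::gaussHermite(gh_nodes)
    negll <- function(par) {
      sigma <- exp(par[p + 1L]); sigma_u <- exp(par[p + 2L])
      xb <- drop(X %*% par[seq_len(p)])
      nodes <- sqrt(2) * gh$x
      logw <- log(gh$w) - 0.5 * log(pi)
      ps <- matrix(0, nlevels(subj), length(nodes))
      at_lo <- y <= lo; at_hi <- y >= hi; mid <- !(at_lo | at_hi)
      for (k in seq_along(nodes)) {
        m_k <- xb + sigma_u * nodes[k]
        ll <- numeric(length(y))
        ll[at_lo] <- stats::pnorm((lo - m_k[at_lo]) / sigma, log.p = TRUE)
        ll[at_hi] <- stats::pnorm((m_k[at_hi] - hi) / sigma, log.p = TRUE)
        ll[mid] <- stats::dnorm(y[mid], m_k[mid], sigma, log = TRUE)
        ps[, k] <- rowsum(ll, subj)[, 1L] + logw[k]
      }
      mx <- apply(ps, 1L, max)
      v <- -sum(mx + log(rowSums(exp(ps - mx))))
      if (!is.finite(v)) 1e10 else v
    }
    start <- c(start, log(0.1))
  } else {
    negll <- function(par) .tobit_negll(par, y, X, lo, hi)
  }
  opt <- stats::optim(start, negll, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-10))
  hess <- stats::optimHess(opt$par, negll)
  V <- tryCatch(solve(hess), error = function(e)
    matrix(NA_real_, length(opt$par), length(opt$par)))
  beta <- stats::setNames(opt$par[seq_len(p)], colnames(X))
  xb <- drop(X %*% beta)
  .mapfit("tobit", beta, sqrt(pmax(diag(V)[seq_len(p)], 0)),
          -opt$value, length(opt$par), length(y),
          pmin(pmax(xb, lo), hi), d$terms,
          converged = opt$convergence == 0L,
          sigma = unname(exp(opt$par[p + 1L])),
          sigma_u = if (random_intercept) unname(exp(opt$par[p + 2L])) else 0,
          limits = limits, vcov = V)
}

# Check (pinball) loss of quantile regression.
.check_loss <- function(r, tau) sum(r * (tau - (r < 0)))

# Smoothed check loss: tau*r + eps*log(1 + exp(-r/eps)), computed stably.
.smooth_check <- function(r, tau, eps) {
  s <- r / eps
  sum(tau * r + eps * (pmax(-s, 0) + log1p(exp(-abs(s)))))
}

# LAD / quantile-regression solver: iteratively reweighted least squares
# on the check loss with a shrinking smoothing floor, polished by BFGS on
# the smoothed loss.  Solutions at the median can be non-unique (the check
# loss is piecewise linear); the solver returns one minimizer.
.lad_fit <- function(X, y, tau = 0.5, maxit = 80L, tol = 1e-10) {
  beta <- stats::lm.fit(X, y)$coefficients
  beta[!is.finite(beta)] <- 0
  eps <- 1e-2
  loss_old <- Inf
  for (it in seq_len(maxit)) {
    r <- y - drop(X %*% beta)
    w <- abs(tau - (r < 0)) / pmax(abs(r), eps)
    fit <- tryCatch(stats::lm.wfit(X, y, w), error = function(e) NULL)
    if (is.null(fit)) break
    beta_new <- fit$coefficients
    beta_new[!is.finite(beta_new)] <- beta[!is.finite(beta_new)]
    loss <- .check_loss(y - drop(X %*% beta_new), tau)
    if (loss <= loss_old) beta <- beta_new
    if (abs(loss_old - loss) < tol * (abs(loss) + 1)) {
      if (eps <= 1e-7) break
      eps <- eps / 10
    }
    loss_old <- loss
  }
  polish <- stats::optim(beta, function(b)
    .smooth_check(y - drop(X %*% b), tau, 1e-6),
    method = "BFGS", control = list(maxit = 200, reltol = 1e-12))
  if (.check_loss(y - drop(X %*% polish$par), tau) <=
      .check_loss(y - drop(X %*% beta), tau)) beta <- polish$par
  stats::setNames(beta, colnames(X))
}

#' Quantile (LAD) mapping model
#'
#' Minimizes the check loss `sum rho_tau(y - X beta)`; at `tau = 0.5` this
#' is least absolute deviation regression, whose intercept-only fit is the
#' sample median.  Standard errors, when requested, come from a
#' nonparametric bootstrap resampling subjects (clusters) when a subject
#' column is given, observations otherwise.  The reported log-likelihood
#' is the asymmetric-Laplace pseudo-likelihood (used only for AIC-style
#' comparison on the same data).
#'
#' @inheritParams fit_linear
#' @param tau quantile level in (0, 1); 0.5 gives the conditional median.
#' @param boot_se bootstrap resamples for standard errors (0 skips them).
#' @return A `"mapfit"` object with `model_kind = "quantile"`.
#' @export
fit_quantile <- function(formula, data, tau = 0.5, subject = NULL,
                         boot_se = 200L) {
  d <- .design(formula, data)
  beta <- .lad_fit(d$X, d$y, tau)
  fitted <- drop(d$X %*% beta)
  r <- d$y - fitted
  n <- length(d$y)
  sigma_al <- mean(r * (tau - (r < 0)))
  ll <- n * log(tau * (1 - tau)) - n * log(sigma_al) - n
  se <- .boot_se_lad(formula, data, tau, subject, boot_se, clad = FALSE)
  if (length(se) != length(beta)) se <- rep(NA_real_, length(beta))
  .mapfit("quantile", beta, se, ll, length(beta) + 1L, n, fitted, d$terms,
          tau = tau, pseudo_loglik = TRUE)
}

.boot_se_lad <- function(formula, data, tau, subject, B, clad,
                         lower = 0, upper = 1) {
  if (B <= 0) return(rep(NA_real_, 1L))
  cluster <- if (!is.null(subject)) data[[subject]] else seq_len(nrow(data))
  ids <- unique(cluster)
  boots <- replicate(B, {
    pick <- sample(ids, length(ids), replace = TRUE)
    db <- do.call(rbind, lapply(pick, function(g)
      data[cluster == g, , drop = FALSE]))
    db <- stats::setNames(db, names(data))
    tryCatch({
      d <- .design(formula, db)
      if (clad) .clad_iterate(d$X, d$y, tau, lower, upper)$beta
      else .lad_fit(d$X, d$y, tau)
    }, error = function(e) NULL)
  }, simplify = FALSE)
  boots <- do.call(rbind, boots[!vapply(boots, is.null, logical(1))])
  if (is.null(boots) || nrow(boots) < 10L) return(rep(NA_real_, 1L))
  apply(boots, 2L, stats::sd)
}

# Powell-type CLAD iteration: alternate a LAD fit on the current
# uncensored-prediction subset with recomputation of which observations
# have X beta inside (lower, upper), until the active set stabilizes.
.clad_iterate <- function(X, y, tau, lower, upper, max_iter = 50L) {
  beta <- .lad_fit(X, y, tau)
  active_old <- rep(TRUE, length(y))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    pred <- drop(X %*% beta)
    active <- pred > lower & pred < upper
    if (!any(active)) stop("CLAD active set is empty: no predictions lie ",
                           "strictly inside (", lower, ", ", upper, ")")
    if (identical(active, active_old) && it > 1L) { converged <- TRUE; break }
    beta <- .lad_fit(X[active, , drop = FALSE], y[active], tau)
    active_old <- active
  }
  list(beta = beta, active = active_old, iterations = it,
       converged = converged)
}

#' Censored least absolute deviation (CLAD) mapping model
#'
#' Powell's median-regression estimator for a response censored at the
#' interval limits, computed by iterative LAD: alternate a LAD fit on the
#' observations whose current predictions lie strictly inside the limits
#' with recomputation of that active set, until it stabilizes (iteration
#' cap 50).  Predictions are censored to the limits, so none fall outside
#' `[lower, upper]`.  The estimator is consistent but not efficient;
#' standard errors come from a nonparametric cluster bootstrap.
#'
#' @inheritParams fit_quantile
#' @param lower,upper censoring limits (default 0 and 1).
#' @param max_iter iteration cap for the active-set loop.
#' @return A `"mapfit"` object with `model_kind = "clad"`.
#' @export
fit_clad <- function(formula, data, tau = 0.5, lower = 0, upper = 1,
                     subject = NULL, boot_se = 200L, max_iter = 50L) {
  d <- .design(formula, data)
  res <- .clad_iterate(d$X, d$y, tau, lower, upper, max_iter)
  fitted <- pmin(pmax(drop(d$X %*% res$beta), lower), upper)
  se <- .boot_se_lad(formula, data, tau, subject, boot_se, clad = TRUE,
                     lower = lower, upper = upper)
  if (length(se) != length(res$beta)) se <- rep(NA_real_, length(res$beta))
  .mapfit("clad", res$beta, se, NA_real_, length(res$beta), length(d$y),
          fitted, d$terms, converged = res$converged, tau = tau,
          limits = c(lower, upper), iterations = res$iterations,
          active_n = sum(res$active))
}

#' Predict utilities from a benchmark mapping fit
#'
#' @param object a `"mapfit"` object.
#' @param newdata optional data frame; defaults to the fitted values.
#' @param type `"default"` applies each model's own prediction rule
#'   (censored to the limits for tobit and CLAD, unbounded for linear,
#'   quadratic and quantile); `"latent"` returns the uncensored linear
#'   predictor for all kinds.
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.mapfit <- function(object, newdata = NULL,
                           type = c("default", "latent"), ...) {
  type <- match.arg(type)
  if (is.null(newdata) && type == "default") return(object$fitted)
  if (is.null(newdata)) {
    # latent predictions on the fitting data
    if (object$model_kind %in% c("tobit", "clad")) {
      # refitting the linear predictor from stored pieces is not possible
      # without the design; mapfit stores fitted censored values, so latent
      # values are only available via newdata for these kinds
      stop("latent predictions on the fitting data require newdata")
    }
    return(object$fitted)
  }
  if (!is.null(object$squared)) {
    newdata <- .augment_squares(newdata, object$squared)
  }
  tt <- stats::delete.response(object$terms)
  X <- stats::model.matrix(tt, stats::model.frame(
    tt, newdata, na.action = stats::na.pass))
  if (ncol(X) != length(object$coefficients)) {
    stop("newdata is not conformable with the fitted design")
  }
  pred <- drop(X %*% object$coefficients)
  if (type == "latent") return(pred)
  if (object$model_kind == "tobit") {
    pred <- pmin(pmax(pred, object$limits[1L]), object$limits[2L])
  } else if (object$model_kind == "clad") {
    pred <- pmin(pmax(pred, object$limits[1L]), object$limits[2L])
  }
  pred
}

#' @export
coef.mapfit <- function(object, ...) object$coefficients

#' @export
logLik.mapfit <- function(object, ...) {
  structure(object$loglik, df = object$df, nobs = object$nobs,
            class = "logLik")
}

#' @export
nobs.mapfit <- function(object, ...) object$nobs

#' @export
print.mapfit <- function(x, ...) {
  cat(sprintf("Mapping model: %s (n = %d)\n", x$model_kind, x$nobs))
  if (!is.null(x$tau)) cat(sprintf("tau = %.2f\n", x$tau))
  cat("Coefficients:\n")
  print(signif(x$coefficients, 4))
  if (!is.null(x$sigma_u) && x$sigma_u > 0) {
    cat(sprintf("Random intercept SD: %.4f\n", x$sigma_u))
  }
  if (is.finite(x$loglik)) {
    cat(sprintf("logLik %.2f%s  AIC %.2f\n", x$loglik,
                if (isTRUE(x$pseudo_loglik)) " (pseudo)" else "",
                2 * x$df - 2 * x$loglik))
  }
  if (!x$converged) cat("WARNING: did not converge\n")
  invisible(x)
}

#' Fit any of the six mapping models by name
#'
#' Dispatcher used by the validation and pipeline layers: `"zoib"` calls
#' [zoib()], the other kinds call the corresponding comparator.
#'
#' @param method one of `"zoib"`, `"linear"`, `"tobit"`, `"quadratic"`,
#'   `"quantile"`, `"clad"`.
#' @param formula mean-model formula.
#' @param data a data frame.
#' @param ... passed to the underlying fitting function.
#' @return A `"zoib"` or `"mapfit"` object.
#' @export
fit_mapping <- function(method = c("zoib", "linear", "tobit", "quadratic",
                                   "quantile", "clad"),
                        formula, data, ...) {
  method <- match.arg(method)
  switch(method,
         zoib = zoib(formula, data, ...),
         linear = fit_linear(formula, data, ...),
         tobit = fit_tobit(formula, data, ...),
         quadratic = fit_quadratic(formula, data, ...),
         quantile = fit_quantile(formula, data, ...),
         clad = fit_clad(formula, data, ...))
}
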