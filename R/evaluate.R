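#' Core fit metrics for a mapping model
#'
#' Computes the Table-2-style metric bundle from observed and predicted
#' utilities: `RMSE = sqrt(mean((o - p)^2))`, `MAE = mean(|o - p|)`, `R2`
#' (by default the squared Pearson correlation of observed and predicted;
#' `1 - SSE/SST` is also reported), the predicted mean with its
#' descriptive standard error `SD(pred)/sqrt(n)` and 95% CI, and the
#' percentage of predictions above 1 and below 0 (the valid UK index
#' range being -0.59 to 1).
#'
#' @param observed,predicted equal-length numeric vectors.
#' @return A list of class `"validation_report"`.
#' @examples
#' fit_metrics(c(0, 0.5, 1), c(0.1, 0.5, 0.9))
#' @export
fit_metrics <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) == 0L) {
    stop("observed and predicted must be non-empty and of equal length")
  }
  ok <- stats::complete.cases(observed, predicted)
  o <- observed[ok]; p <- predicted[ok]
  n <- length(o)
  rmse <- sqrt(mean((o - p)^2))
  mae <- mean(abs(o - p))
  r2 <- if (stats::sd(p) == 0 || stats::sd(o) == 0) {
    NA_real_  # constant predictions: correlation-based R2 undefined
  } else {
    stats::cor(o, p)^2
  }
  r2_sse <- 1 - sum((o - p)^2) / sum((o - mean(o))^2)
  pm <- mean(p)
  pse <- stats::sd(p) / sqrt(n)
  structure(list(
    n_obs = n, r2 = r2, r2_sse = r2_sse, mae = mae, rmse = rmse,
    predicted_mean = pm, predicted_se = pse,
    predicted_ci = pm + c(-1, 1) * stats::qnorm(0.975) * pse,
    observed_mean = mean(o),
    pct_pred_gt1 = 100 * mean(p > 1),
    pct_pred_lt0 = 100 * mean(p < 0),
    aic = NA_real_
  ), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Validation report (n = %d)\n", x$n_obs))
  cat(sprintf("  R2 %.3f (corr)  %.3f (1-SSE/SST)%s\n",
              x$r2, x$r2_sse,
              if (is.na(x$r2)) "  [constant predictions]" else ""))
  cat(sprintf("  MAE %.4f   RMSE %.4f\n", x$mae, x$rmse))
  cat(sprintf("  Predicted mean %.4f (SE %.4f), 95%% CI [%.4f, %.4f]\n",
              x$predicted_mean, x$predicted_se,
              x$predicted_ci[1], x$predicted_ci[2]))
  cat(sprintf("  Observed mean %.4f\n", x$observed_mean))
  cat(sprintf("  Predicted > 1: %.2f%%   Predicted < 0: %.2f%%\n",
              x$pct_pred_gt1, x$pct_pred_lt0))
  if (is.finite(x$aic)) cat(sprintf("  AIC %.1f\n", x$aic))
  if (!is.null(x$bands)) {
    cat("  Within +/-t of observed:\n")
    print(round(x$bands, 3))
  }
  invisible(x)
}

#' Proportions of predictions within relative bands of the observed values
#'
#' For each threshold `t` (default 5% to 30%), the fraction of
#' observations with `|p - o| / |o| <= t`.  Observations with observed
#' value 0 have no defined relative error; they are excluded from the
#' denominators and counted in the `n_excluded_zero` attribute.
#'
#' @param observed,predicted equal-length numeric vectors.
#' @param thresholds relative thresholds.
#' @return Named vector of proportions (non-decreasing in the threshold),
#'   with attribute `n_excluded_zero`.
#' @export
prediction_bands <- function(observed, predicted,
                             thresholds = seq(0.05, 0.30, by = 0.05)) {
  nz <- observed != 0
  rel <- abs(predicted[nz] - observed[nz]) / abs(observed[nz])
  # small slack so exact-ratio cases are not lost to floating-point noise
  out <- vapply(thresholds, function(t) mean(rel <= t + 1e-12), numeric(1))
  names(out) <- paste0("within_", round(100 * thresholds), "pct")
  attr(out, "n_excluded_zero") <- sum(!nz)
  out
}

#' Mean predicted utility by observed health state
#'
#' Orders the distinct observed health states from 11111 to 33333 (by
#' decreasing tariff value, then code) and reports, per state, the number
#' of observations, the observed mean utility and the mean model
#' prediction.  Attaches a Poor/Good over-prediction summary: the mean
#' prediction error below and above a cut state (defaults 11321, the
#' state below which observed and predicted values typically diverge).
#'
#' @param data dataset containing the health-state column and the model
#'   covariates.
#' @param fit a `"zoib"` or `"mapfit"` model (or a numeric vector of
#'   predictions).
#' @param state_col name of the health-state column.
#' @param utility_col name of the observed-utility column.
#' @param cut_state Poor/Good cut state code.
#' @param predict_type prediction type passed to `predict` for zoib fits.
#' @return A data frame (state, utility_tariff, n, observed_mean,
#'   predicted_mean) with attribute `overprediction`.
#' @export
health_state_curve <- function(data, fit, state_col = "eq5d_state",
                               utility_col = "eq5d_utility",
                               cut_state = "11321",
                               predict_type = "mixture") {
  if (!state_col %in% names(data)) {
    stop("column '", state_col, "' not found in data")
  }
  pred <- if (is.numeric(fit)) fit
  else if (inherits(fit, "zoib")) predict(fit, data, type = predict_type)
  else predict(fit, data)
  states <- data[[state_col]]
  tar <- tto_value(unique(states))
  ord <- order(-tar, names(tar))
  lev <- names(tar)[ord]
  obs <- data[[utility_col]]
  agg <- data.frame(
    state = lev,
    utility_tariff = unname(tar[lev]),
    n = as.integer(table(factor(states, levels = lev))),
    observed_mean = as.numeric(tapply(obs, factor(states, levels = lev),
                                      mean)),
    predicted_mean = as.numeric(tapply(pred, factor(states, levels = lev),
                                       mean)),
    stringsAsFactors = FALSE
  )
  cut_val <- unname(tto_value(cut_state))
  poor <- agg$utility_tariff < cut_val
  werr <- function(sub) {
    if (!any(sub)) return(NA_real_)
    sum((agg$predicted_mean - agg$observed_mean)[sub] * agg$n[sub]) /
      sum(agg$n[sub])
  }
  attr(agg, "overprediction") <- c(
    cut_state = cut_state, cut_value = cut_val,
    mean_error_poor = werr(poor), mean_error_good = werr(!poor))
  agg
}

#' Train on one dataset, validate on another
#'
#' Fits a mapping model on `train` and evaluates all metrics on `test`
#' without refitting.  The in-sample AIC is attached only when the two
#' datasets are the same object: AIC is comparable only between fits on
#' the same data, so cross-dataset reports carry `aic = NA`.
#'
#' @param train,test data frames with identical column schema.
#' @param method model kind, see [fit_mapping()].
#' @param formula mean-model formula.
#' @param predict_type prediction type for zoib fits (`"mixture"` by
#'   default, the model's expected utility).
#' @param ... passed to the fitting function.
#' @return A `"validation_report"` with prediction bands, plus the fit in
#'   attribute `fit`.
#' @export
cross_validate <- function(train, test, method, formula,
                           predict_type = "mixture", ...) {
  if (!identical(sort(names(train)), sort(names(test)))) {
    stop("train and test datasets have different column schemas")
  }
  fit <- fit_mapping(method, formula, train, ...)
  resp <- all.vars(formula)[1L]
  pred <- if (inherits(fit, "zoib")) {
    predict(fit, test, type = predict_type)
  } else {
    predict(fit, test)
  }
  obs <- test[[resp]]
  ok <- stats::complete.cases(obs, pred)
  rep <- fit_metrics(obs[ok], pred[ok])
  rep$bands <- prediction_bands(obs[ok], pred[ok])
  if (identical(train, test)) rep$aic <- stats::AIC(fit)
  attr(rep, "fit") <- fit
  rep
}

#' Monte-Carlo coverage of a predicted-mean confidence interval
#'
#' The calibration engine for the uncertainty analysis: for each
#' replicate, simulate a dataset, fit the model, form the 95% CI of the
#' predicted mean, and record whether it contains `target_mean`.  Returns
#' the containment percentage with its binomial standard error.
#' Replicate-level fitting failures are excluded and counted.
#'
#' @param simulate_fn function of the replicate index returning a dataset.
#' @param fit_fn function of a dataset returning a fitted model.
#' @param ci_fn function of a fit returning a length-2 CI.  The default
#'   uses [predicted_mean_ci()] for zoib fits (an influence-function CI
#'   for the mean mixture prediction) and the descriptive
#'   `mean +/- 1.96 SD(pred)/sqrt(n)` band otherwise.
#' @param target_mean the mean whose containment is assessed.
#' @param n_replicates number of Monte-Carlo replicates (>= 100 advised).
#' @return A list with `coverage_pct`, `se_pct`, `n_used`, `n_failed`.
#' @export
coverage_study <- function(simulate_fn, fit_fn, target_mean,
                           n_replicates = 500, ci_fn = NULL) {
  if (is.null(ci_fn)) {
    ci_fn <- function(fit) {
      if (inherits(fit, "zoib")) return(predicted_mean_ci(fit)$ci)
      p <- predict(fit)
      mean(p) + c(-1, 1) * stats::qnorm(0.975) * stats::sd(p) /
        sqrt(length(p))
    }
  }
  hits <- logical(0)
  n_failed <- 0L
  for (i in seq_len(n_replicates)) {
    res <- tryCatch({
      d <- simulate_fn(i)
      ci <- ci_fn(fit_fn(d))
      ci[1L] <= target_mean && target_mean <= ci[2L]
    }, error = function(e) NA)
    if (is.na(res)) n_failed <- n_failed + 1L else hits <- c(hits, res)
  }
  n_used <- length(hits)
  if (n_used == 0L) stop("all replicates failed")
  cov <- 100 * mean(hits)
  list(coverage_pct = cov,
       se_pct = 100 * sqrt(mean(hits) * (1 - mean(hits)) / n_used),
       n_used = n_used, n_failed = n_failed)
}
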