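#' Run a configured analysis stage
#'
#' Reproducible driver tying the modules together.  A configuration is a
#' named list (or a YAML file path) with at least `verb` and `out_dir`; a
#' `seed` is mandatory for any stochastic verb.  Verbs:
#'
#' * `simulate` - `preset` (name or YAML path): writes `dataset.csv`.
#' * `fit` - `data` (path) or `preset` + `seed`; `models` (default all
#'   six); `covariates` (default the 15 domains); `subject`: writes one
#'   coefficient table per model and `comparison.csv` with logLik, AIC,
#'   RMSE, MAE, R2 and out-of-range percentages.
#' * `validate` - `train`, `test` (paths), `model`: writes `report.csv`.
#' * `coverage` - `model`, `preset`, `n_replicates`, `target_mean`:
#'   writes `coverage.csv`.
#' * `qaly` - `arms` (see [qaly_psa()]), `n_sims`: writes `qaly.csv`.
#'
#' Every run echoes its configuration, seed and package version into
#' `run_log.yaml` in `out_dir`; identical config + seed gives identical
#' artifacts.
#'
#' @param config a named list or path to a YAML file.
#' @return The stage result, invisibly; artifacts are written to
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  verb <- config$verb
  if (is.null(verb)) stop("config$verb is required")
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("config$out_dir is required")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stochastic <- verb %in% c("simulate", "coverage", "qaly")
  if (stochastic && is.null(config$seed)) {
    stop("config$seed is mandatory for verb '", verb, "'")
  }
  result <- tryCatch(
    switch(verb,
           simulate = .verb_simulate(config),
           fit = .verb_fit(config),
           validate = .verb_validate(config),
           coverage = .verb_coverage(config),
           qaly = .verb_qaly(config),
           stop("unknown verb: ", verb)),
    error = function(e) stop("pipeline stage '", verb, "' failed: ",
                             conditionMessage(e), call. = FALSE))
  log <- list(config = config,
              package_version = as.character(utils::packageVersion("eq5dmap")),
              r_version = R.version.string)
  yaml::write_yaml(log, file.path(out_dir, "run_log.yaml"))
  invisible(result)
}

.verb_simulate <- function(cfg) {
  preset <- trial_preset(cfg$preset)
  d <- simulate_trial(preset, seed = cfg$seed)
  write_trial_data(d, file.path(cfg$out_dir, "dataset.csv"))
  d
}

.pipeline_data <- function(cfg, key = "data") {
  if (!is.null(cfg[[key]])) return(read_trial_data(cfg[[key]]))
  if (!is.null(cfg$preset)) {
    return(simulate_trial(trial_preset(cfg$preset), seed = cfg$seed))
  }
  stop("config needs '", key, "' (a file path) or 'preset'")
}

.verb_fit <- function(cfg) {
  d <- .pipeline_data(cfg)
  models <- cfg$models %||% c("zoib", "linear", "tobit", "quadratic",
                              "quantile", "clad")
  covs <- cfg$covariates %||% qlq_domains
  f <- mapping_formula(covariates = covs)
  subject <- cfg$subject %||% "subject_id"
  rows <- list(); fits <- list()
  for (m in models) {
    fit <- switch(m,
                  quantile = fit_quantile(f, d, subject = subject,
                                          boot_se = cfg$boot_se %||% 0L),
                  clad = fit_clad(f, d, subject = subject,
                                  boot_se = cfg$boot_se %||% 0L),
                  zoib = zoib(f, d, subject = subject),
                  fit_mapping(m, f, d, subject = subject))
    fits[[m]] <- fit
    pred <- if (inherits(fit, "zoib")) predict(fit, type = "mixture")
            else predict(fit)
    resp <- d[[all.vars(f)[1L]]]
    met <- fit_metrics(pmax(resp, 0), pred)
    co <- if (inherits(fit, "zoib")) coef(fit) else coef(fit)
    se <- if (inherits(fit, "zoib")) {
      sqrt(pmax(diag(vcov(fit)), 0))[seq_along(co)]
    } else fit$se
    utils::write.csv(
      data.frame(term = names(co), estimate = unname(co),
                 se = if (length(se) == length(co)) unname(se) else NA),
      file.path(cfg$out_dir, paste0("fit_", m, ".csv")), row.names = FALSE)
    ll <- tryCatch(as.numeric(logLik(fit)), error = function(e) NA)
    rows[[m]] <- data.frame(
      model = m, loglik = ll,
      aic = tryCatch(stats::AIC(fit), error = function(e) NA),
      r2 = met$r2, mae = met$mae, rmse = met$rmse,
      predicted_mean = met$predicted_mean,
      predicted_se = met$predicted_se,
      pct_pred_gt1 = met$pct_pred_gt1, pct_pred_lt0 = met$pct_pred_lt0)
  }
  comp <- do.call(rbind, rows)
  utils::write.csv(comp, file.path(cfg$out_dir, "comparison.csv"),
                   row.names = FALSE)
  list(fits = fits, comparison = comp)
}

.verb_validate <- function(cfg) {
  train <- .pipeline_data(cfg, "train")
  test <- if (!is.null(cfg$test)) read_trial_data(cfg$test) else train
  covs <- cfg$covariates %||% qlq_domains
  rep <- cross_validate(train, test, cfg$model %||% "zoib",
                        mapping_formula(covariates = covs))
  out <- data.frame(metric = c("r2", "mae", "rmse", "predicted_mean",
                               "predicted_se", "pct_pred_gt1",
                               "pct_pred_lt0", "aic", names(rep$bands)),
                    value = c(rep$r2, rep$mae, rep$rmse,
                              rep$predicted_mean, rep$predicted_se,
                              rep$pct_pred_gt1, rep$pct_pred_lt0, rep$aic,
                              unname(rep$bands)))
  utils::write.csv(out, file.path(cfg$out_dir, "report.csv"),
                   row.names = FALSE)
  rep
}

.verb_coverage <- function(cfg) {
  preset <- trial_preset(cfg$preset)
  covs <- cfg$covariates %||% c("PF", "PA", "QL")
  f <- mapping_formula(covariates = covs)
  model <- cfg$model %||% "zoib"
  base_seed <- cfg$seed
  res <- coverage_study(
    simulate_fn = function(i) simulate_trial(preset,
                                             seed = base_seed + i),
    fit_fn = function(d) fit_mapping(model, f, d),
    target_mean = cfg$target_mean %||% preset$utility$mean,
    n_replicates = cfg$n_replicates %||% 500)
  utils::write.csv(as.data.frame(res),
                   file.path(cfg$out_dir, "coverage.csv"),
                   row.names = FALSE)
  res
}

.verb_qaly <- function(cfg) {
  res <- qaly_psa(cfg$arms, n_sims = cfg$n_sims %||% 10000,
                  seed = cfg$seed)
  out <- data.frame(
    arm = c(res$arms, "difference"),
    mean_qaly = c(res$mean_qaly, res$mean_difference),
    ci_lo = c(res$ci_qaly[, 1], res$ci_difference[1]),
    ci_hi = c(res$ci_qaly[, 2], res$ci_difference[2]))
  utils::write.csv(out, file.path(cfg$out_dir, "qaly.csv"),
                   row.names = FALSE)
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a
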