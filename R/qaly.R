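#' Patient-level QALY
#'
#' A quality-adjusted life year is survival time weighted by utility:
#' `utility * survival_time`, with time converted to years.
#'
#' @param utility mean utility over the period.
#' @param survival_time survival time, in `time_unit`.
#' @param time_unit `"years"` (default), `"months"` or `"days"`.
#' @return QALYs (numeric, vectorized).
#' @examples
#' patient_qaly(0.62, 3, time_unit = "months")  # 0.155
#' @export
patient_qaly <- function(utility, survival_time,
                         time_unit = c("years", "months", "days")) {
  time_unit <- match.arg(time_unit)
  if (any(survival_time < 0, na.rm = TRUE)) {
    stop("survival times must be non-negative")
  }
  years <- switch(time_unit, years = survival_time,
                  months = survival_time / 12,
                  days = survival_time / 365.25)
  utility * years
}

#' Arm-level QALY as a weighted pre/post-progression sum
#'
#' `pre_utility * mean_pfs + post_utility * (mean_os - mean_pfs)`: mean
#' progression-free time valued at the pre-progression utility, plus mean
#' post-progression time valued at the post-progression utility.  No
#' discounting or half-cycle correction is applied.
#'
#' @param pre_utility,post_utility mean utilities before and after
#'   progression.
#' @param mean_pfs,mean_os mean progression-free and overall survival, in
#'   years, with `mean_pfs <= mean_os`.
#' @return A list with `qaly`, `pre_component`, `post_component`.
#' @examples
#' group_qaly(0.8, 0.4, mean_pfs = 0.5, mean_os = 1.0)  # total 0.6
#' @export
group_qaly <- function(pre_utility, post_utility, mean_pfs, mean_os) {
  if (any(mean_pfs > mean_os)) {
    stop("mean PFS cannot exceed mean OS")
  }
  pre <- pre_utility * mean_pfs
  post <- post_utility * (mean_os - mean_pfs)
  list(qaly = pre + post, pre_component = pre, post_component = post)
}

#' Probabilistic sensitivity analysis of QALY estimates
#'
#' Monte-Carlo propagation of survival and utility uncertainty into
#' arm-level QALYs and the between-arm difference.  Per replicate and per
#' arm: overall and progression-free survival times are simulated for `n`
#' subjects by [simulate_survival()], their means taken (the area under
#' the exponential survival curve), pre- and post-progression mean
#' utilities drawn by [simulate_utility_margin()], and the arm QALY formed
#' by [group_qaly()].  The difference is `arm 1 - arm 2` in the order the
#' arms are supplied.
#'
#' @param arms a named list of exactly two arm specifications, each a list
#'   with `lambda_os` (and `lambda_pfs` or `kappa`), `n` (subjects), and
#'   `pre_utility` / `post_utility`, each a list with `mean`, `sd`,
#'   `p_one` for the utility simulator.  A degenerate utility can be
#'   given as a single number.
#' @param n_sims number of Monte-Carlo replicates.
#' @param seed optional integer seed.
#' @return An object of class `"qaly_psa"`: per-arm mean QALYs, the mean
#'   difference, 95% percentile intervals, per-arm pre/post decomposition
#'   and the replicate draws.
#' @export
qaly_psa <- function(arms, n_sims = 10000, seed = NULL) {
  if (length(arms) != 2L || is.null(names(arms))) {
    stop("arms must be a named list of two arm specifications")
  }
  if (!is.null(seed)) set.seed(seed)
  make_sampler <- function(spec) {
    if (is.numeric(spec) && length(spec) == 1L) {
      u <- spec
      function(n) rep(u, n)
    } else {
      utility_margin_sampler(spec$mean, spec$sd, spec$p_one)
    }
  }
  samplers <- lapply(arms, function(a)
    list(pre = make_sampler(a$pre_utility),
         post = make_sampler(a$post_utility)))
  one_arm <- function(a, s_u) {
    s <- simulate_survival(a$lambda_os, a$lambda_pfs, n = a$n,
                           kappa = a$kappa)
    pre <- mean(s_u$pre(a$n))
    post <- mean(s_u$post(a$n))
    g <- group_qaly(pre, post, mean(s$pfs), mean(s$os))
    c(qaly = g$qaly, pre = g$pre_component, post = g$post_component,
      mean_os = mean(s$os), mean_pfs = mean(s$pfs))
  }
  draws <- array(NA_real_, c(n_sims, 2L, 5L),
                 dimnames = list(NULL, names(arms),
                                 c("qaly", "pre", "post", "mean_os",
                                   "mean_pfs")))
  n_failed <- 0L
  for (i in seq_len(n_sims)) {
    res <- tryCatch(
      mapply(one_arm, arms, samplers, SIMPLIFY = TRUE),
      error = function(e) NULL)
    if (is.null(res)) n_failed <- n_failed + 1L else draws[i, , ] <- t(res)
  }
  ok <- !is.na(draws[, 1L, 1L])
  q1 <- draws[ok, 1L, "qaly"]; q2 <- draws[ok, 2L, "qaly"]
  diff <- q1 - q2
  pct <- function(x) stats::quantile(x, c(0.025, 0.975), names = FALSE)
  structure(list(
    arms = names(arms),
    mean_qaly = c(mean(q1), mean(q2)),
    mean_difference = mean(diff),
    ci_qaly = rbind(pct(q1), pct(q2)),
    ci_difference = pct(diff),
    decomposition = apply(draws[ok, , c("pre", "post"), drop = FALSE],
                          c(2L, 3L), mean),
    n_sims = sum(ok), n_failed = n_failed,
    draws = draws[ok, , , drop = FALSE]
  ), class = "qaly_psa")
}

#' @export
print.qaly_psa <- function(x, ...) {
  cat(sprintf("QALY probabilistic sensitivity analysis (%d simulations",
              x$n_sims))
  if (x$n_failed > 0) cat(sprintf(", %d failed", x$n_failed))
  cat(")\n")
  for (i in 1:2) {
    cat(sprintf("  %-12s mean QALY %.3f  [%.3f, %.3f]\n", x$arms[i],
                x$mean_qaly[i], x$ci_qaly[i, 1], x$ci_qaly[i, 2]))
  }
  cat(sprintf("  difference   %.3f  [%.3f, %.3f]\n", x$mean_difference,
              x$ci_difference[1], x$ci_difference[2]))
  invisible(x)
}
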