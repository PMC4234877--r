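#' Load a simulated-trial preset or configuration file
#'
#' Two presets ship with the package: `"topical"`, a large poor-prognosis
#' lung-cancer trial profile (670 subjects, 2038 observations, utility
#' mean/SD 0.61/0.29, 10% ceiling mass at 1), and `"soccar"`, a smaller
#' better-prognosis profile (130 subjects, 1002 observations, mean/SD
#' 0.75/0.23, 25% mass at 1).  A custom YAML file with the same structure
#' can be given by path.
#'
#' @param name `"topical"`, `"soccar"`, or a path to a YAML config.
#' @return A simulation configuration (a named list).
#' @export
trial_preset <- function(name = c("topical", "soccar")) {
  if (is.null(name) || !length(name) || !nzchar(name[1L])) {
    stop("a preset name ('topical', 'soccar') or config path is required")
  }
  path <- if (file.exists(name[1L])) {
    name[1L]
  } else {
    name <- match.arg(name)
    system.file("extdata", "presets", paste0(name, ".yaml"),
                package = "eq5dmap")
  }
  cfg <- yaml::read_yaml(path)
  needed <- c("n_subjects", "n_obs", "max_visits", "icc", "utility",
              "domains", "factor_loading_utility")
  missing <- setdiff(needed, names(cfg))
  if (length(missing)) {
    stop("simulation config is missing fields: ",
         paste(missing, collapse = ", "))
  }
  cfg
}

#' QLQ-C30 domain column names
#'
#' The 15 domain scores in the fixed column order used throughout the
#' package: five function scales (PF, RF, EF, CF, SF), eight symptom
#' scales (FA, NV, PA, DY, SL, AP, CO, DI), global health (QL) and
#' financial impact (FI), all on 0-100.
#'
#' @format Character vector of length 15.
#' @export
qlq_domains <- c("PF", "RF", "EF", "CF", "SF", "FA", "NV", "PA", "DY",
                 "SL", "AP", "CO", "DI", "QL", "FI")

# Conditional moments of the continuous utility component given the
# overall target mean/SD and the point masses p1 at 1 and p0 at (about) 0:
#   mean_total = p1 + pc m_c,  E[Y^2] = p1 + pc (v_c + m_c^2),
# with pc = 1 - p0 - p1.
.continuous_utility_moments <- function(mean, sd, p1, p0 = 0) {
  pc <- 1 - p0 - p1
  m_c <- (mean - p1) / pc
  ey2 <- sd^2 + mean^2
  v_c <- (ey2 - p1) / pc - m_c^2
  if (pc <= 0 || m_c <= 0 || m_c >= 1 || v_c <= 0) {
    stop("utility targets (mean = ", mean, ", sd = ", sd, ", p_one = ",
         p1, ", p_zero = ", p0, ") leave no feasible continuous component")
  }
  list(mean = m_c, sd = sqrt(v_c))
}

#' Simulate a correlated QLQ-C30 / EQ-5D-3L trial dataset
#'
#' Generates a long-format trial dataset (subject x visit) whose 15 domain
#' scores and utility match configured means, SDs and a configured
#' correlation structure, using the Vale-Maurelli construction: draw
#' multivariate normals with the adjusted intermediate correlation matrix,
#' apply per-variable Fleishman cubic transforms (targets derived from
#' moment-matched scaled beta shapes), rescale to the target mean/SD, then
#' truncate domains to `[0, 100]` and utilities to `[lower, 1]`, placing
#' the configured point mass at utility 1 on the observations with the
#' highest latent utility.  Within-subject dependence comes from a shared
#' subject-level component of the latent normals (intra-class correlation
#' `icc`).
#'
#' Truncation and boundary inflation distort the realized moments
#' slightly; the achieved-vs-target summary is attached as
#' `attr(result, "moment_report")` rather than corrected away.
#'
#' @param config a configuration from [trial_preset()].
#' @param seed integer seed; every run is reproducible from config + seed.
#' @return A data frame with columns `subject_id`, `arm`, `visit`, the 15
#'   domain scores and `eq5d_utility`, plus a `moment_report` attribute.
#' @examples
#' d <- simulate_trial(trial_preset("soccar"), seed = 1)
#' mean(d$eq5d_utility); mean(d$eq5d_utility == 1)
#' @export
simulate_trial <- function(config, seed) {
  if (!missing(seed)) set.seed(seed)
  doms <- names(config$domains)
  if (!setequal(doms, qlq_domains)) {
    stop("config must describe exactly the 15 QLQ-C30 domains")
  }
  doms <- qlq_domains
  k <- length(doms) + 1L  # utility first, then domains

  u_cfg <- config$utility
  p_zero <- u_cfg$p_zero %||% 0
  p_neg <- u_cfg$p_neg %||% 0
  cc <- .continuous_utility_moments(u_cfg$mean, u_cfg$sd, u_cfg$p_one,
                                    p_zero + p_neg)

  # per-variable Fleishman targets from moment-matched beta shapes
  targets <- vector("list", k)
  targets[[1L]] <- .beta_shape_targets(cc$mean, cc$sd, 0, 1)
  for (j in seq_along(doms)) {
    dcfg <- config$domains[[doms[j]]]
    targets[[j + 1L]] <- .beta_shape_targets(dcfg$mean, dcfg$sd, 0, 100)
  }
  coefs <- lapply(targets, function(t)
    solve_fleishman(t["skewness"], t["kurtosis_excess"]))

  # one-factor target correlation structure
  lambda_u <- config$factor_loading_utility
  r_u <- vapply(config$domains[doms], `[[`, numeric(1), "r")
  lambda <- c(lambda_u, r_u / lambda_u)
  if (any(abs(lambda) >= 1)) {
    stop("factor loadings exceed 1; lower the domain-utility correlations ",
         "or raise factor_loading_utility")
  }
  R <- tcrossprod(lambda); diag(R) <- 1
  dimnames(R) <- list(c("utility", doms), c("utility", doms))
  Rz <- intermediate_correlation(R, coefs)
  L <- chol(Rz)

  # subject x visit layout with a dropout-like visit-count distribution
  ns <- config$n_subjects; n_obs <- config$n_obs
  visits <- .visit_counts(ns, n_obs, config$max_visits)
  subj_of_obs <- rep(seq_len(ns), visits)
  visit_idx <- unlist(lapply(visits, seq_len))

  icc <- config$icc
  Zs <- matrix(stats::rnorm(ns * k), ns, k) %*% L
  Zv <- matrix(stats::rnorm(n_obs * k), n_obs, k) %*% L
  Z <- sqrt(icc) * Zs[subj_of_obs, , drop = FALSE] + sqrt(1 - icc) * Zv

  out <- matrix(0, n_obs, k)
  for (j in seq_len(k)) {
    out[, j] <- fleishman_transform(Z[, j], coefs[[j]])
  }
  # utility margin: rank-based point mass at 1 on the highest latent
  # values, a small mass at 0 and a tiny worse-than-death fraction on the
  # lowest, and the continuous component rescaled to its conditional
  # moments on (0, 1); transform spill below 0 joins the zero mass and is
  # measured in the moment report rather than corrected
  u_lat <- out[, 1L]
  n1 <- round(u_cfg$p_one * n_obs)
  n_neg <- round(p_neg * n_obs)
  n0 <- round(p_zero * n_obs)
  rk <- rank(u_lat, ties.method = "first")
  at_one <- rk > n_obs - n1
  at_neg <- rk <= n_neg
  at_zero <- rk > n_neg & rk <= n_neg + n0
  mid <- !(at_one | at_neg | at_zero)
  u <- numeric(n_obs)
  u[at_one] <- 1
  if (n_neg > 0L) {
    neg_lo <- max(u_cfg$lower, -0.06)
    u[at_neg] <- sort(stats::runif(n_neg, neg_lo, -0.005))[rank(u_lat[at_neg])]
  }
  v <- u_lat[mid]
  v <- cc$mean + (v - mean(v)) * cc$sd / stats::sd(v)
  u[mid] <- pmax(pmin(v, 1 - 1e-6), 0)

  scores <- matrix(0, n_obs, length(doms),
                   dimnames = list(NULL, doms))
  for (j in seq_along(doms)) {
    dcfg <- config$domains[[doms[j]]]
    scores[, j] <- pmin(pmax(dcfg$mean + dcfg$sd * out[, j + 1L], 0), 100)
  }

  arms <- if (!is.null(config$arms)) config$arms else c("A", "B")
  arm_of_subj <- rep_len(arms, ns)[sample.int(ns)]
  dat <- data.frame(
    subject_id = sprintf("S%04d", subj_of_obs),
    arm = arm_of_subj[subj_of_obs],
    visit = visit_idx,
    scores,
    eq5d_state = .nearest_health_state(u),
    eq5d_utility = u,
    stringsAsFactors = FALSE
  )
  ach_r <- stats::cor(u, scores)[1L, ]
  attr(dat, "moment_report") <- list(
    utility = c(target_mean = u_cfg$mean, achieved_mean = mean(u),
                target_sd = u_cfg$sd, achieved_sd = stats::sd(u),
                target_p_one = u_cfg$p_one, achieved_p_one = mean(u == 1),
                frac_at_zero = mean(u == 0),
                frac_below_zero = mean(u < 0)),
    domain_utility_cor = rbind(target = r_u, achieved = ach_r)
  )
  dat
}

# Visit counts per subject: truncated-geometric draws adjusted to an
# exact total, emulating monthly follow-up with dropout.
.visit_counts <- function(n_subjects, n_obs, max_visits) {
  target_mean <- n_obs / n_subjects
  if (target_mean < 1 || target_mean > max_visits) {
    stop("n_obs implies between 1 and max_visits visits per subject")
  }
  p <- 1 / target_mean
  v <- pmin(1L + stats::rgeom(n_subjects, p), max_visits)
  excess <- sum(v) - n_obs
  while (excess > 0L) {
    i <- sample(which(v > 1L), 1L)
    v[i] <- v[i] - 1L; excess <- excess - 1L
  }
  while (excess < 0L) {
    i <- sample(which(v < max_visits), 1L)
    v[i] <- v[i] + 1L; excess <- excess + 1L
  }
  v
}

#' Simulate utility draws from a marginal trial profile
#'
#' Draws utilities from the same marginal construction as
#' [simulate_trial()] (Fleishman continuous component plus point mass at
#' 1), without the multivariate structure.  Used by the QALY
#' probabilistic sensitivity analysis.
#'
#' @param mean,sd overall target mean and SD.
#' @param p_one point mass at utility 1.
#' @param n number of draws.
#' @param p_zero point mass at utility 0.
#' @return Numeric vector of utilities.
#' @export
simulate_utility_margin <- function(mean, sd, p_one, n, p_zero = 0) {
  sampler <- utility_margin_sampler(mean, sd, p_one, p_zero)
  sampler(n)
}

#' @rdname simulate_utility_margin
#' @return `utility_margin_sampler()` returns a function of `n` drawing
#'   utilities, with the Fleishman solve done once up front (useful in
#'   Monte-Carlo loops).
#' @export
utility_margin_sampler <- function(mean, sd, p_one, p_zero = 0) {
  if (sd == 0) {
    m <- mean
    return(function(n) rep(m, n))
  }
  cc <- .continuous_utility_moments(mean, sd, p_one, p_zero)
  t <- .beta_shape_targets(cc$mean, cc$sd, 0, 1)
  f <- solve_fleishman(t["skewness"], t["kurtosis_excess"])
  function(n) .draw_utility_margin(n, cc, f, p_one, p_zero)
}

.draw_utility_margin <- function(n, cc, f, p_one, p_zero) {
  y <- fleishman_transform(stats::rnorm(n), f)
  rk <- rank(y, ties.method = "first")
  n1 <- stats::rbinom(1L, n, p_one)
  n0 <- stats::rbinom(1L, n, p_zero)
  at_one <- rk > n - n1
  at_zero <- rk <= n0
  mid <- !(at_one | at_zero)
  u <- numeric(n)
  u[at_one] <- 1
  if (any(mid)) {
    v <- y[mid]
    v <- cc$mean + (v - mean(v)) * cc$sd / stats::sd(v)
    u[mid] <- pmax(pmin(v, 1 - 1e-6), 0)
  }
  u
}

#' Simulate exponential overall and progression-free survival
#'
#' Overall survival is drawn by the exponential inverse CDF
#' `OS = -log(1 - x) / lambda_os` with `x ~ Uniform(0, 1)`.
#' Progression-free survival is constructed as `PFS = OS * U^(1/kappa)`
#' with an independent uniform `U`, which guarantees `PFS < OS` for every
#' subject; when `kappa` is not supplied it is derived from the two
#' hazard rates as `kappa = lambda_os / (lambda_pfs - lambda_os)`, so
#' that `E[PFS] = 1 / lambda_pfs`.  Optional administrative censoring at
#' `censor_time` records event indicators.
#'
#' @param lambda_os overall-survival hazard rate (> 0), per unit time.
#' @param lambda_pfs progression hazard rate (> `lambda_os`); used to
#'   derive `kappa` when that is `NULL`.
#' @param n number of subjects.
#' @param kappa PFS shape parameter (> 0); overrides `lambda_pfs`.
#' @param censor_time optional administrative censoring time.
#' @return A data frame with columns `os`, `pfs`, `os_event`, `pfs_event`.
#' @examples
#' s <- simulate_survival(lambda_os = 1, lambda_pfs = 2, n = 1000)
#' all(s$pfs < s$os)
#' @export
simulate_survival <- function(lambda_os, lambda_pfs = NULL, n,
                              kappa = NULL, censor_time = NULL) {
  if (lambda_os <= 0) stop("hazard rates must be positive")
  if (is.null(kappa)) {
    if (is.null(lambda_pfs)) {
      kappa <- 1
    } else {
      if (lambda_pfs <= lambda_os) {
        stop("lambda_pfs must exceed lambda_os (progression precedes death)")
      }
      kappa <- lambda_os / (lambda_pfs - lambda_os)
    }
  }
  os <- -log(1 - stats::runif(n)) / lambda_os
  pfs <- os * stats::runif(n)^(1 / kappa)
  if (!is.null(censor_time)) {
    os_event <- os <= censor_time
    pfs_event <- pfs <= censor_time
    os <- pmin(os, censor_time)
    pfs <- pmin(pfs, censor_time)
  } else {
    os_event <- pfs_event <- rep(TRUE, n)
  }
  data.frame(os = os, pfs = pfs, os_event = os_event,
             pfs_event = pfs_event)
}
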