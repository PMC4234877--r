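#' Build a mapping formula from domain names
#'
#' @param response response column (default `eq5d_utility`).
#' @param covariates covariate columns (default all 15 QLQ-C30 domains).
#' @return A formula.
#' @export
mapping_formula <- function(response = "eq5d_utility",
                            covariates = qlq_domains) {
  stats::reformulate(covariates, response = response)
}

.trial_schema <- function() {
  list(required = c("subject_id", "visit", qlq_domains),
       optional = c("arm", "eq5d_state", "eq5d_utility", "os", "pfs",
                    "os_event", "pfs_event"))
}

#' Read and validate a long-format trial dataset
#'
#' Reads delimited text (one row per subject x visit) with the fixed
#' column schema: `subject_id`, `visit`, optionally `arm`, the 15 domain
#' scores (0-100), and `eq5d_state` (5-digit codes) and/or `eq5d_utility`
#' (in `[-0.59, 1]`); optional survival columns `os`, `pfs`, `os_event`,
#' `pfs_event`.  Column names outside the schema are a hard error unless
#' remapped via `rename`.  When `eq5d_utility` is absent it is derived
#' from the states via the tariff; when both are present, rows whose
#' utility disagrees with the tariff value of their state beyond
#' `utility_tol` trigger a warning listing the rows (the default tolerance
#' covers the half-gap granularity of the UK tariff values).  A per-column
#' missing-count report and the negative-utility count are attached as
#' attributes.
#'
#' @param path delimited text file with a header.
#' @param sep field separator (default `","`; use `"\t"` for TSV).
#' @param rename optional named character vector mapping file column
#'   names to schema names, e.g. `c(IN = "SL", AL = "AP")` for the
#'   insomnia/appetite naming duality.
#' @param tariff tariff decrements, see [load_tariff()].
#' @param utility_tol tolerance for the state/utility consistency check.
#' @return A validated data frame.
#' @export
read_trial_data <- function(path, sep = ",", rename = NULL,
                            tariff = load_tariff(), utility_tol = 0.06) {
  dat <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE,
                           colClasses = NA, comment.char = "")
  if (nrow(dat) == 0L) stop("empty dataset: ", path)
  if (!is.null(rename)) {
    idx <- match(names(rename), names(dat))
    names(dat)[idx[!is.na(idx)]] <- rename[!is.na(idx)]
  }
  sch <- .trial_schema()
  unknown <- setdiff(names(dat), c(sch$required, sch$optional))
  if (length(unknown)) {
    stop("unknown columns (not in the trial schema): ",
         paste(unknown, collapse = ", "))
  }
  missing_req <- setdiff(sch$required, names(dat))
  if (length(missing_req)) {
    stop("missing required columns: ", paste(missing_req, collapse = ", "))
  }
  if (!("eq5d_state" %in% names(dat)) &&
      !("eq5d_utility" %in% names(dat))) {
    stop("need eq5d_state or eq5d_utility")
  }
  if (anyDuplicated(dat[c("subject_id", "visit")])) {
    stop("(subject_id, visit) pairs are not unique")
  }
  for (v in qlq_domains) {
    bad <- which(!is.na(dat[[v]]) & (dat[[v]] < 0 | dat[[v]] > 100))
    if (length(bad)) {
      stop("domain ", v, " outside [0, 100] at rows: ",
           paste(utils::head(bad, 10L), collapse = ", "))
    }
  }
  if ("eq5d_state" %in% names(dat)) {
    dat$eq5d_state <- as.character(dat$eq5d_state)
    state_util <- unname(tto_value(dat$eq5d_state, tariff))
    if (!"eq5d_utility" %in% names(dat)) {
      dat$eq5d_utility <- state_util
    } else {
      off <- which(!is.na(dat$eq5d_utility) &
                     abs(dat$eq5d_utility - state_util) > utility_tol)
      if (length(off)) {
        warning("eq5d_utility disagrees with tariff(eq5d_state) beyond ",
                utility_tol, " at rows: ",
                paste(utils::head(off, 20L), collapse = ", "))
      }
    }
  }
  u <- dat$eq5d_utility
  if (any(u < -0.595 | u > 1, na.rm = TRUE)) {
    stop("eq5d_utility outside [-0.59, 1] at rows: ",
         paste(utils::head(which(u < -0.595 | u > 1), 10L), collapse = ", "))
  }
  attr(dat, "missing_report") <- vapply(dat, function(x) sum(is.na(x)),
                                        integer(1))
  attr(dat, "n_negative_utility") <- sum(u < 0, na.rm = TRUE)
  dat
}

#' @rdname read_trial_data
#' @param data a trial data frame.
#' @export
write_trial_data <- function(data, path, sep = ",") {
  utils::write.table(data, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
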