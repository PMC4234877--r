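#' EQ-5D-3L dimension codes
#'
#' The five EQ-5D-3L dimensions in their standard order: Mobility (MO),
#' Self-Care (SC), Usual Activities (UA), Pain/Discomfort (PD) and
#' Anxiety/Depression (AD).
#'
#' @format A character vector of length 5.
#' @export
eq5d_dimensions <- c("MO", "SC", "UA", "PD", "AD")

#' Parse EQ-5D-3L health-state codes
#'
#' An EQ-5D-3L health state is a 5-digit string, one digit per dimension in
#' the order Mobility, Self-Care, Usual Activities, Pain/Discomfort,
#' Anxiety/Depression, each digit being a severity level 1 (no problems),
#' 2 (some problems) or 3 (extreme problems).  `"11111"` is full health and
#' `"33333"` the worst state.
#'
#' @param code character vector of 5-digit state codes, e.g. `"21222"`.
#' @return An integer matrix with one row per state and columns
#'   `MO, SC, UA, PD, AD` containing levels 1-3.  Row names are the codes.
#' @examples
#' parse_health_state("21222")
#' parse_health_state(c("11111", "33333"))
#' @export
parse_health_state <- function(code) {
  code <- as.character(code)
  bad_len <- nchar(code) != 5L | is.na(code)
  if (any(bad_len)) {
    stop("invalid health state: ", paste(code[bad_len], collapse = ", "),
         " (must be exactly 5 digits)")
  }
  chars <- matrix(unlist(strsplit(code, "")), ncol = 5L, byrow = TRUE)
  for (j in seq_len(5L)) {
    bad <- !chars[, j] %in% c("1", "2", "3")
    if (any(bad)) {
      stop("invalid health state '", code[which(bad)[1L]],
           "': digit at position ", j, " is '", chars[which(bad)[1L], j],
           "' (levels must be 1, 2 or 3)")
    }
  }
  levels <- matrix(as.integer(chars), ncol = 5L,
                   dimnames = list(code, eq5d_dimensions))
  levels
}

#' Load an EQ-5D-3L tariff coefficient table
#'
#' Reads a value-set decrement table of the additive form used by the UK TTO
#' (MVH A1) tariff: a constant decrement applied when any dimension is above
#' level 1, a decrement per dimension-level, and an extra "N3" decrement when
#' any dimension is at level 3.  The UK TTO table ships with the package and
#' is the default; alternative tariffs with the same structure can be
#' supplied as a CSV with columns `term` and `decrement`.
#'
#' @param path path to a tariff CSV; default is the shipped UK TTO table.
#' @return A named numeric vector of decrements.
#' @export
load_tariff <- function(path = system.file("extdata", "uk_tto_tariff.csv",
                                           package = "eq5dmap")) {
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("term", "decrement") %in% names(tab))) {
    stop("tariff file must have columns 'term' and 'decrement'")
  }
  coefs <- stats::setNames(tab$decrement, tab$term)
  needed <- c("constant", "n3",
              paste0(rep(eq5d_dimensions, each = 2L), "_", 2:3))
  missing <- setdiff(needed, names(coefs))
  if (length(missing)) {
    stop("tariff file is missing terms: ", paste(missing, collapse = ", "))
  }
  coefs
}

#' UK TTO tariff utility of EQ-5D-3L health states
#'
#' Applies an additive TTO value set (by default the UK MVH A1 tariff) to
#' health states: utility 1 minus a constant decrement if any dimension is
#' above level 1, minus per-dimension level-2/level-3 decrements, minus an
#' N3 decrement if any dimension is at level 3.  The resulting UK index
#' ranges from -0.594 (state 33333, printed as -0.59) to 1 (state 11111).
#'
#' @param state character vector of 5-digit codes, or a level matrix from
#'   [parse_health_state()].
#' @param tariff named decrement vector from [load_tariff()].
#' @return Numeric vector of utilities, named by state code.
#' @examples
#' tto_value("21222")   # 0.62
#' tto_value("33333")   # -0.594
#' @export
tto_value <- function(state, tariff = load_tariff()) {
  levels <- if (is.matrix(state)) state else parse_health_state(state)
  any_above_1 <- rowSums(levels > 1L) > 0L
  any_at_3 <- rowSums(levels == 3L) > 0L
  u <- 1 - tariff["constant"] * any_above_1 - tariff["n3"] * any_at_3
  for (j in seq_len(5L)) {
    dim <- eq5d_dimensions[j]
    u <- u - tariff[paste0(dim, "_2")] * (levels[, j] == 2L) -
      tariff[paste0(dim, "_3")] * (levels[, j] == 3L)
  }
  stats::setNames(as.numeric(u), rownames(levels))
}

#' Rescale a bounded utility to the unit interval
#'
#' Maps a value on `[a, b]` to `[0, 1]` by `(y - a) / (b - a)`, the
#' transformation under which a beta likelihood can be applied to responses
#' on an arbitrary bounded interval.  For instance a utility of -0.1 on
#' `[-0.53, 1]` maps to 0.28.  Inverted by [unit_to_interval()].
#'
#' @param y numeric vector in `[a, b]`.
#' @param a,b interval endpoints, `a < b`.
#' @return Numeric vector in `[0, 1]`.
#' @export
rescale_to_unit <- function(y, a, b) {
  if (!is.numeric(a) || !is.numeric(b) || a >= b) {
    stop("invalid interval: need a < b")
  }
  if (any(y < a | y > b, na.rm = TRUE)) {
    stop("values outside [", a, ", ", b, "] cannot be rescaled")
  }
  (y - a) / (b - a)
}

#' @rdname rescale_to_unit
#' @param v numeric vector in `[0, 1]`.
#' @export
unit_to_interval <- function(v, a, b) {
  if (!is.numeric(a) || !is.numeric(b) || a >= b) {
    stop("invalid interval: need a < b")
  }
  a + v * (b - a)
}

#' All 243 EQ-5D-3L health states and their tariff values
#'
#' @param tariff named decrement vector from [load_tariff()].
#' @return A data frame with columns `state` and `utility`, ordered from
#'   11111 to 33333.
#' @export
all_health_states <- function(tariff = load_tariff()) {
  g <- expand.grid(AD = 1:3, PD = 1:3, UA = 1:3, SC = 1:3, MO = 1:3)
  codes <- sprintf("%d%d%d%d%d", g$MO, g$SC, g$UA, g$PD, g$AD)
  codes <- sort(codes)
  data.frame(state = codes, utility = unname(tto_value(codes, tariff)),
             stringsAsFactors = FALSE)
}

# Nearest health state (by tariff value) for each utility; used to attach
# plausible state labels to simulated utilities.
.nearest_health_state <- function(u, states = all_health_states()) {
  idx <- vapply(u, function(v) which.min(abs(states$utility - v)),
                integer(1))
  states$state[idx]
}

#' Floor negative utilities at zero
#'
#' States worse than death have negative tariff values; when fewer than
#' about half a percent of observations are negative the modelling layer
#' sets them to 0 rather than rescaling the whole response.  Returns the
#' floored vector with attributes `n_floored` and `frac_floored` recording
#' how many values were raised.
#'
#' @param y numeric vector of utilities, all `<= 1`.
#' @return `pmax(y, 0)` with floor-count attributes.
#' @export
floor_negative <- function(y) {
  if (any(y > 1, na.rm = TRUE)) {
    stop("utilities above 1 are outside the valid range")
  }
  n_floored <- sum(y < 0, na.rm = TRUE)
  out <- pmax(y, 0)
  attr(out, "n_floored") <- n_floored
  attr(out, "frac_floored") <- n_floored / sum(!is.na(y))
  out
}
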