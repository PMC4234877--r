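#' Fleishman power-method coefficients
#'
#' Solves for the cubic-polynomial coefficients of the Fleishman power
#' method: `Y = a + b Z + c Z^2 + d Z^3` with `Z` standard normal, such
#' that `Y` has mean 0, variance 1 and the target skewness and excess
#' kurtosis.  The constraint `a = -c` enforces the zero mean; the
#' remaining three moment equations are solved numerically.
#'
#' The moment pair must be feasible: any distribution satisfies
#' `kurtosis_excess >= skewness^2 - 2`, and the cubic transform covers a
#' slightly smaller region still; infeasible targets raise an error naming
#' the violated bound.
#'
#' @param skewness target third standardized moment.
#' @param kurtosis_excess target excess kurtosis (normal = 0).
#' @return A list with elements `a`, `b`, `c`, `d` and the achieved
#'   moment residual.
#' @examples
#' solve_fleishman(0, 0)        # identity: b = 1, a = c = d = 0
#' solve_fleishman(1.0, 1.5)
#' @export
solve_fleishman <- function(skewness, kurtosis_excess) {
  g1 <- skewness; g2 <- kurtosis_excess
  if (g2 < g1^2 - 2) {
    stop("infeasible moments: excess kurtosis (", g2,
         ") is below the universal bound skewness^2 - 2 = ", g1^2 - 2)
  }
  if (abs(g1) < 1e-12 && abs(g2) < 1e-12) {
    return(list(a = 0, b = 1, c = 0, d = 0, residual = 0))
  }
  eqs <- function(par) {
    b <- par[1L]; c <- par[2L]; d <- par[3L]
    c(b^2 + 6 * b * d + 2 * c^2 + 15 * d^2 - 1,
      2 * c * (b^2 + 24 * b * d + 105 * d^2 + 2) - g1,
      24 * (b * d + c^2 * (1 + b^2 + 28 * b * d) +
              d^2 * (12 + 48 * b * d + 141 * c^2 + 225 * d^2)) - g2)
  }
  obj <- function(par) sum(eqs(par)^2)
  starts <- list(c(1, g1 / 8, 0),
                 c(0.9, g1 / 6, 0.02 * sign(g2 + 1e-12)),
                 c(0.8, g1 / 5, 0.05))
  best <- NULL
  for (s in starts) {
    par <- tryCatch(
      suppressWarnings(pracma::fsolve(eqs, s, maxiter = 200)$x),
      error = function(e) NULL)
    if (is.null(par)) {
      par <- stats::optim(s, obj, method = "BFGS",
                          control = list(maxit = 2000,
                                         reltol = 1e-16))$par
    }
    o <- list(par = par, value = obj(par))
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (best$value > 1e-10) {
    stop("Fleishman system has no solution at skewness = ", g1,
         ", excess kurtosis = ", g2,
         " (moment pair outside the power-method region; residual ",
         signif(best$value, 3), ")")
  }
  b <- best$par[1L]; c <- best$par[2L]; d <- best$par[3L]
  if (b < 0) { b <- -b; c <- c; d <- -d }  # pick the increasing branch
  list(a = -c, b = b, c = c, d = d, residual = best$value)
}

#' Apply a Fleishman transform
#'
#' @param z standard-normal draws.
#' @param coefs coefficients from [solve_fleishman()].
#' @return `a + b z + c z^2 + d z^3`.
#' @export
fleishman_transform <- function(z, coefs) {
  coefs$a + coefs$b * z + coefs$c * z^2 + coefs$d * z^3
}

# Population correlation of two Fleishman variates as a function of the
# correlation rho of their underlying normals (Vale-Maurelli identity):
# r = rho (b1 b2 + 3 b1 d2 + 3 d1 b2 + 9 d1 d2) + rho^2 (2 c1 c2)
#     + rho^3 (6 d1 d2)
.fleishman_pair_cor <- function(rho, f1, f2) {
  rho * (f1$b * f2$b + 3 * f1$b * f2$d + 3 * f1$d * f2$b +
           9 * f1$d * f2$d) +
    rho^2 * (2 * f1$c * f2$c) + rho^3 * (6 * f1$d * f2$d)
}

#' Intermediate correlation matrix for Vale-Maurelli simulation
#'
#' Given target product-moment correlations of the transformed variables
#' and each variable's Fleishman coefficients, solves the cubic
#' Vale-Maurelli identity per pair (by root-finding on `[-1, 1]`) for the
#' correlations the underlying normals must have, so that the transformed
#' draws attain the targets.
#'
#' @param target target correlation matrix (symmetric, unit diagonal).
#' @param coef_list list of [solve_fleishman()] results, one per variable.
#' @return The intermediate correlation matrix.  An error is raised if it
#'   is not positive semi-definite (with a pointer to `Matrix::nearPD()`
#'   for repairing a hand-built target).
#' @export
intermediate_correlation <- function(target, coef_list) {
  k <- nrow(target)
  out <- diag(k)
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      r <- target[i, j]
      if (r == 0) { out[i, j] <- out[j, i] <- 0; next }
      f <- function(rho) .fleishman_pair_cor(rho, coef_list[[i]],
                                             coef_list[[j]]) - r
      # the cubic can be non-monotone for strongly opposite-skewed pairs:
      # bracket all roots on a grid and keep the smallest in magnitude
      grid <- seq(-0.9999, 0.9999, length.out = 401L)
      fg <- vapply(grid, f, numeric(1))
      cross <- which(fg[-1L] * fg[-length(fg)] <= 0)
      if (!length(cross)) {
        stop("no intermediate correlation reproduces target r = ", r,
             " for variable pair (", i, ", ", j, ")")
      }
      roots <- vapply(cross, function(ix)
        stats::uniroot(f, grid[c(ix, ix + 1L)], tol = 1e-10)$root,
        numeric(1))
      out[i, j] <- out[j, i] <- roots[which.min(abs(roots))]
    }
  }
  ev <- eigen(out, symmetric = TRUE)
  adjusted <- FALSE
  if (min(ev$values) < -1e-8) {
    if (min(ev$values) < -0.02) {
      stop("intermediate correlation matrix is not positive semi-definite ",
           "(smallest eigenvalue ", signif(min(ev$values), 3),
           "); consider projecting the target with Matrix::nearPD()")
    }
    # marginal violation from the per-pair adjustment: clip eigenvalues
    # and restore the unit diagonal
    lam <- pmax(ev$values, 1e-8)
    out <- ev$vectors %*% diag(lam) %*% t(ev$vectors)
    out <- stats::cov2cor(out)
    adjusted <- TRUE
  }
  dimnames(out) <- dimnames(target)
  attr(out, "psd_adjusted") <- adjusted
  out
}

#' Sample moments of a Fleishman variate (Monte-Carlo check)
#'
#' @param coefs coefficients from [solve_fleishman()].
#' @param n number of draws.
#' @return Named vector with mean, sd, skewness, excess kurtosis.
#' @export
fleishman_moments <- function(coefs, n = 1e6) {
  z <- stats::rnorm(n)
  y <- fleishman_transform(z, coefs)
  m <- mean(y); s <- stats::sd(y)
  c(mean = m, sd = s,
    skewness = mean((y - m)^3) / s^3,
    kurtosis_excess = mean((y - m)^4) / s^4 - 3)
}

#' Minimum excess kurtosis attainable by the Fleishman transform
#'
#' For a given skewness, the cubic power method can only reach excess
#' kurtosis above a boundary curve (about -1.151 at skewness 0, rising
#' with skewness).  Computed by minimizing the kurtosis
#' expression under the variance and skewness moment constraints
#' (quadratic penalty, Nelder-Mead).
#'
#' @param skewness target skewness.
#' @return The boundary excess kurtosis.
#' @export
fleishman_boundary <- function(skewness) {
  g1 <- skewness
  obj <- function(par) {
    b <- par[1L]; c <- par[2L]; d <- par[3L]
    v <- b^2 + 6 * b * d + 2 * c^2 + 15 * d^2 - 1
    s <- 2 * c * (b^2 + 24 * b * d + 105 * d^2 + 2) - g1
    k <- 24 * (b * d + c^2 * (1 + b^2 + 28 * b * d) +
                 d^2 * (12 + 48 * b * d + 141 * c^2 + 225 * d^2))
    k + 1e6 * (v^2 + s^2)
  }
  o <- stats::optim(c(1, g1 / 8, -0.05), obj, method = "Nelder-Mead",
                    control = list(maxit = 20000, reltol = 1e-14))
  o <- stats::optim(o$par, obj, method = "Nelder-Mead",
                    control = list(maxit = 20000, reltol = 1e-14))
  o$value
}

# Skewness and excess kurtosis of the Beta distribution matching a given
# mean and sd on [lo, hi]; used to derive per-variable Fleishman targets
# from the configured marginal shape.  Falls back to the nearest feasible
# kurtosis when the beta shape sits below the power-method boundary.
.beta_shape_targets <- function(mean, sd, lo, hi) {
  m <- (mean - lo) / (hi - lo)
  s2 <- (sd / (hi - lo))^2
  s2 <- min(s2, 0.98 * m * (1 - m))  # keep the beta shape feasible
  sh <- moments_to_shapes(m, s2)
  a <- sh$alpha; b <- sh$beta
  skew <- 2 * (b - a) * sqrt(a + b + 1) / ((a + b + 2) * sqrt(a * b))
  kurt <- 6 * ((a - b)^2 * (a + b + 1) - a * b * (a + b + 2)) /
    (a * b * (a + b + 2) * (a + b + 3))
  kurt_min <- fleishman_boundary(skew) + 0.05
  c(skewness = skew, kurtosis_excess = max(kurt, kurt_min))
}
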