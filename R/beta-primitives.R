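#' Beta distribution: shape and mean/precision parameterizations
#'
#' A Beta(alpha, beta) response can equivalently be written in terms of its
#' mean `mu = alpha / (alpha + beta)` and precision `phi = alpha + beta`,
#' with variance `mu (1 - mu) / (phi + 1)`.  `moments_to_shapes()` inverts
#' the mean/variance relations by the method of moments:
#' `alpha = mu * (mu (1 - mu) / sigma2 - 1)` and
#' `beta = (1 - mu) * (mu (1 - mu) / sigma2 - 1)`.
#' `shapes_to_moments()` is its inverse.
#'
#' @param mu mean in (0, 1).
#' @param sigma2 variance, `0 < sigma2 < mu * (1 - mu)`.
#' @return `moments_to_shapes()`: a list with `alpha`, `beta`, `mu`, `phi`,
#'   `sigma2`.  `shapes_to_moments()`: a list with `mu`, `sigma2`.
#' @examples
#' moments_to_shapes(0.5, 1 / 12)  # the uniform: alpha = beta = 1
#' moments_to_shapes(0.61, 0.29^2) # beta shape < 1
#' @export
moments_to_shapes <- function(mu, sigma2) {
  if (any(mu <= 0 | mu >= 1)) stop("mu must lie strictly in (0, 1)")
  if (any(sigma2 <= 0)) stop("variance must be positive")
  if (any(sigma2 >= mu * (1 - mu))) {
    stop("infeasible variance: need sigma2 < mu * (1 - mu) = ",
         paste(signif(mu * (1 - mu), 4), collapse = ", "))
  }
  nu <- mu * (1 - mu) / sigma2 - 1
  list(alpha = mu * nu, beta = (1 - mu) * nu,
       mu = mu, phi = nu, sigma2 = sigma2)
}

#' @rdname moments_to_shapes
#' @param alpha,beta beta shape parameters, both positive.
#' @export
shapes_to_moments <- function(alpha, beta) {
  if (any(alpha <= 0 | beta <= 0)) stop("shape parameters must be positive")
  phi <- alpha + beta
  mu <- alpha / phi
  list(mu = mu, sigma2 = mu * (1 - mu) / (phi + 1))
}

#' Log-density of the beta distribution in mean/precision form
#'
#' `log f(y | mu, phi)` with `f(y | mu, phi) =
#' Gamma(phi) / (Gamma(mu phi) Gamma((1 - mu) phi)) *
#' y^(mu phi - 1) (1 - y)^((1 - mu) phi - 1)`, i.e. the Beta(alpha, beta)
#' density at `alpha = mu phi`, `beta = (1 - mu) phi`.  Boundary values 0
#' and 1 carry no beta density; in the inflated model they belong to the
#' point-mass components.
#'
#' @param y response strictly inside (0, 1).
#' @param mu mean in (0, 1).
#' @param phi precision, positive.
#' @return Log-density, vectorized over its arguments.
#' @export
beta_logdensity <- function(y, mu, phi) {
  if (any(y <= 0 | y >= 1)) {
    stop("beta_logdensity is defined on (0, 1); boundary values are ",
         "handled by the inflation components")
  }
  if (any(mu <= 0 | mu >= 1) || any(phi <= 0)) {
    stop("need 0 < mu < 1 and phi > 0")
  }
  stats::dbeta(y, mu * phi, (1 - mu) * phi, log = TRUE)
}

#' Link functions of the beta regression submodels
#'
#' The mean submodel uses a logit link: for linear predictor
#' `omega = X beta`, `mu = exp(omega) / (1 + exp(omega))`, computed
#' overflow-safely; its inverse is `logit(mu)`.  The dispersion submodel
#' uses a log link: `phi = exp(W delta)`.
#'
#' @param eta linear predictor of the mean submodel.
#' @return `mean_link()`: means in (0, 1).  `mean_link_inv()`: logits.
#'   `dispersion_link()`: precisions.
#' @export
mean_link <- function(eta) stats::plogis(eta)

#' @rdname mean_link
#' @param mu mean in (0, 1).
#' @export
mean_link_inv <- function(mu) stats::qlogis(mu)

#' @rdname mean_link
#' @param zeta linear predictor of the dispersion submodel.
#' @export
dispersion_link <- function(zeta) exp(zeta)
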