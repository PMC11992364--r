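#' Normalized steady-state profile for half-domain production
#'
#' The closed-form surface concentration profile for pheromone produced on
#' the half-plane `x < 0` (the illuminated domain) and taken up by
#' receiver cells everywhere, normalized by the far-field value:
#' \deqn{f(x) = \Theta(-x) + \frac{\cos(x/\lambda)}{\pi}\,
#'   \mathrm{sign}(x)\Big(\frac{\pi}{2} - \mathrm{Si}(|x|/\lambda)\Big)
#'   + \frac{\sin(x/\lambda)}{\pi}\, \mathrm{Ci}(|x|/\lambda).}
#' The concentration is `c(x) = c_far * f(x)`. The profile decreases
#' monotonically from 1 deep in the production domain through exactly 1/2
#' at the border to a heavy algebraic tail
#' \eqn{f(x) \approx \lambda/(\pi x)} for \eqn{x \gg \lambda} -- much
#' longer-ranged than the exponential decay of one-dimensional
#' production-degradation systems.
#'
#' For `|x|/lambda < 1e-8` the analytic limit `f = 1/2` is substituted
#' (the `sin(u) Ci(u)` term has a removable singularity at the border).
#'
#' @param x position along the assay axis (um); border at 0, production
#'   domain at `x < 0`. Vectorized.
#' @param lambda decay length (um), > 0.
#' @return Numeric vector of dimensionless values in `[0, 1]`.
#' @examples
#' source_profile(c(-Inf, 0, 735, 7350), lambda = 735)
#' @export
source_profile <- function(x, lambda) {
  if (!is.finite(lambda) || lambda <= 0) stop("`lambda` must be > 0")
  if (any(is.na(x))) stop("`x` must not contain NA")
  u <- abs(x) / lambda
  out <- numeric(length(x))
  inf <- is.infinite(x)
  out[inf & x < 0] <- 1
  out[inf & x > 0] <- 0
  near0 <- !inf & u < 1e-8
  out[near0] <- 0.5
  rest <- !inf & !near0
  if (any(rest)) {
    xr <- x[rest]
    ur <- u[rest]
    sc <- si_ci(ur)
    out[rest] <- as.numeric(xr < 0) +
      cos(xr / lambda) / pi * sign(xr) * (pi / 2 - sc$Si) +
      sin(xr / lambda) / pi * sc$Ci
  }
  out
}

#' Normalized steady-state profile for a perfect-sink half-domain
#'
#' Surface profile when pheromone is produced over the whole surface but a
#' perfect sink (saturating Bar1 protease secretion) occupies `x > 0`:
#' concentration is exactly zero over the entire sink domain, and on the
#' diffusion side it follows the antisymmetrized source profile
#' \deqn{g(x) = 2 f(x) - 1 \quad (x < 0), \qquad g(x) = 0 \quad (x \ge 0),}
#' with the same decay length \eqn{\lambda} as in the sink-free geometry.
#' `g` is continuous at the border (`g(0^-) = 0`) and rises toward 1 far
#' into the diffusion domain with twice the near-border slope of the
#' source case.
#'
#' @inheritParams source_profile
#' @return Numeric vector of dimensionless values in `[0, 1]`; identically
#'   0 for `x >= 0`.
#' @examples
#' sink_profile(c(-2000, -100, 0, 500), lambda = 735)
#' @export
sink_profile <- function(x, lambda) {
  if (!is.finite(lambda) || lambda <= 0) stop("`lambda` must be > 0")
  ifelse(x >= 0, 0, pmax(2 * source_profile(x, lambda) - 1, 0))
}

#' Steady-state concentration in EC50 units
#'
#' Evaluates `c(x) = C * f(x)` (source geometry) or `c(x) = C * g(x)`
#' (perfect-sink geometry), with `C` the far-field concentration in EC50
#' units.
#'
#' @param x positions (um).
#' @param shape a [gradient_shape()].
#' @param geometry `"source"` (production on `x < 0`, uptake everywhere)
#'   or `"sink"` (production everywhere, perfect sink on `x > 0`).
#' @return Concentration values (EC50 units), nonnegative.
#' @examples
#' sh <- gradient_shape(735, 1.45)
#' concentration(0, sh, "source")      # C/2 at the border
#' concentration(500, sh, "sink")      # 0 in the sink domain
#' @export
concentration <- function(x, shape, geometry = c("source", "sink")) {
  stopifnot(inherits(shape, "gradient_shape"))
  geometry <- match.arg(geometry)
  prof <- switch(geometry,
    source = source_profile(x, shape$lambda),
    sink = sink_profile(x, shape$lambda)
  )
  shape$C * prof
}

#' Hill dose-response function
#'
#' Fractional pathway response to a concentration in EC50 units:
#' \eqn{\theta(c) = c^n / (1 + c^n)}, strictly increasing, half-maximal at
#' exactly one EC50. With `n = 1` this is the Michaelian (non-cooperative)
#' form used for the gene-expression channel.
#'
#' @param c concentration (EC50 units), >= 0. Vectorized.
#' @param n Hill coefficient, integer >= 1.
#' @return Response values in `[0, 1)`.
#' @examples
#' hill_response(1, n = 3)      # 0.5 at the EC50 for any n
#' hill_response(1.45, n = 1)   # far-field plateau of the n = 1 channel
#' @export
hill_response <- function(c, n) {
  if (length(n) != 1 || !is.finite(n) || n != round(n) || n < 1)
    stop("`n` must be a single integer >= 1")
  if (any(is.na(c)) || any(c < 0)) stop("`c` must be nonnegative")
  cn <- c^n
  ifelse(is.infinite(cn), 1, cn / (1 + cn))
}

#' Model readout along the gradient
#'
#' The observable response of one channel at positions `x`: the Hill
#' response to the modeled concentration, scaled and offset into readout
#' units, \eqn{\hat\theta(x) = A\,\theta(c(x)) + b}.
#'
#' @param x positions (um).
#' @param shape a [gradient_shape()].
#' @param resp a [response_params()] for the channel.
#' @param geometry `"source"` or `"sink"`.
#' @return Readout values (units of `resp$A`).
#' @examples
#' sh <- gradient_shape(735, 1.45)
#' observed_response(c(-2500, 0, 2500), sh, response_params(1, 1, 0.1))
#' @export
observed_response <- function(x, shape, resp, geometry = c("source", "sink")) {
  stopifnot(inherits(resp, "response_params"))
  geometry <- match.arg(geometry)
  resp$A * hill_response(concentration(x, shape, geometry), resp$n) + resp$b
}

#' Normalize a readout by its theoretical maximum
#'
#' Maps raw readout values onto the dimensionless response scale:
#' baseline-subtract, divide by the amplitude, then divide by the
#' theoretical plateau \eqn{C^n/(1+C^n)} so the far-field production
#' plateau maps to exactly 1. Puts channels with different Hill
#' coefficients and units on a common axis.
#'
#' @param theta_hat raw readout values.
#' @param resp a [response_params()]; `resp$A` must be > 0.
#' @param C far-field concentration (EC50 units).
#' @return Dimensionless values; 1 at the theoretical plateau.
#' @export
normalize_max <- function(theta_hat, resp, C) {
  stopifnot(inherits(resp, "response_params"))
  if (resp$A <= 0) stop("`resp$A` must be > 0 to normalize")
  if (!is.finite(C) || C <= 0) stop("`C` must be > 0")
  plateau <- C^resp$n / (1 + C^resp$n)
  ((theta_hat - resp$b) / resp$A) / plateau
}

#' Finite-difference gradient at the light-dark border
#'
#' The concentration gradient at the border, measured as a centered
#' difference over a scale `delta`:
#' \eqn{[c(-\delta/2) - c(+\delta/2)]/\delta}. The derivative of the
#' closed-form profile diverges logarithmically at the border, so a finite
#' evaluation scale is not an approximation convenience but part of the
#' definition; the default is one cell diameter (5 um), the scale over
#' which a cell could sense a concentration difference.
#'
#' @param shape a [gradient_shape()].
#' @param delta evaluation scale (um), > 0; default 5.
#' @return Border gradient (EC50 units per um), positive, linear in
#'   `shape$C`.
#' @examples
#' border_gradient(gradient_shape(735, 1.45))   # ~3.8e-3 EC50/um
#' @export
border_gradient <- function(shape, delta = 5) {
  stopifnot(inherits(shape, "gradient_shape"))
  if (!is.finite(delta) || delta <= 0) stop("`delta` must be > 0")
  (concentration(-delta / 2, shape, "source") -
     concentration(delta / 2, shape, "source")) / delta
}
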