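#' Microscopic physical parameters of the gradient model
#'
#' Bundles the rates and surface densities entering the reaction-diffusion
#' description: pheromone diffusion against surface uptake by receiver
#' cells sets a single decay length
#' \eqn{\lambda = D/(\Omega \rho_A)}, and the production/uptake balance
#' sets the far-field surface concentration
#' \eqn{c_{far} = r \rho_\alpha / (\Omega \rho_A)}.
#'
#' @param D diffusion coefficient (um^2/s).
#' @param r pheromone production rate per emitter cell (molecules/s).
#' @param rho_alpha emitter (MATalpha) surface density (cells/um^2).
#' @param rho_A receiver (MATa) surface density (cells/um^2).
#' @param Omega per-cell degradation parameter (um^3/s; a rate times a
#'   length cubed).
#' @return An object of class `physical_params` with fields `D`, `r`,
#'   `rho_alpha`, `rho_A`, `Omega` and derived `decay_length` (um) and
#'   `c_far` (same units as `r rho_alpha / (Omega rho_A)`).
#' @examples
#' pp <- physical_params(D = 300, r = 1000, rho_alpha = 0.01,
#'                       rho_A = 0.01, Omega = 40)
#' pp$decay_length
#' @export
physical_params <- function(D, r, rho_alpha, rho_A, Omega) {
  vals <- c(D = D, r = r, rho_alpha = rho_alpha, rho_A = rho_A, Omega = Omega)
  if (!all(is.finite(vals)) || any(vals <= 0))
    stop("all physical parameters must be finite and strictly positive")
  out <- list(
    D = D, r = r, rho_alpha = rho_alpha, rho_A = rho_A, Omega = Omega,
    decay_length = D / (Omega * rho_A),
    c_far = r * rho_alpha / (Omega * rho_A)
  )
  class(out) <- "physical_params"
  out
}

#' @export
print.physical_params <- function(x, ...) {
  cat("Physical parameters of the pheromone gradient model\n")
  cat(sprintf("  D            %.4g um^2/s\n", x$D))
  cat(sprintf("  r            %.4g molecules/s per emitter\n", x$r))
  cat(sprintf("  rho_alpha    %.4g cells/um^2\n", x$rho_alpha))
  cat(sprintf("  rho_A        %.4g cells/um^2\n", x$rho_A))
  cat(sprintf("  Omega        %.4g um^3/s\n", x$Omega))
  cat(sprintf("  decay length %.4g um   (D / (Omega rho_A))\n", x$decay_length))
  cat(sprintf("  c_far        %.4g      (r rho_alpha / (Omega rho_A))\n", x$c_far))
  invisible(x)
}

#' Effective gradient shape parameters
#'
#' The two parameters the binned single-cell data actually constrain: the
#' decay length `lambda` (um) and the far-field concentration `C` in EC50
#' units (the concentration far inside the production domain, divided by
#' the EC50 of the gene-expression response).
#'
#' @param lambda decay length (um), > 0.
#' @param C far-field concentration (EC50 units), > 0.
#' @return An object of class `gradient_shape`.
#' @seealso [from_physical()] to derive a shape from microscopic rates.
#' @examples
#' gradient_shape(lambda = 735, C = 1.45)
#' @export
gradient_shape <- function(lambda, C) {
  if (!is.finite(lambda) || lambda <= 0) stop("`lambda` must be > 0")
  if (!is.finite(C) || C <= 0) stop("`C` must be > 0")
  structure(list(lambda = lambda, C = C), class = "gradient_shape")
}

#' @export
print.gradient_shape <- function(x, ...) {
  cat(sprintf("Gradient shape: lambda = %.4g um, C = %.4g EC50 units\n",
              x$lambda, x$C))
  invisible(x)
}

#' Derive a gradient shape from physical parameters
#'
#' Converts microscopic rates to the two effective parameters, given the
#' EC50 of the gene-expression response in the same concentration units as
#' the physical far-field amplitude.
#'
#' @param phys a [physical_params()] object.
#' @param ec50 half-maximal response concentration, in the units of
#'   `phys$c_far`.
#' @return A [gradient_shape()] with `lambda = phys$decay_length` and
#'   `C = phys$c_far / ec50`.
#' @export
from_physical <- function(phys, ec50) {
  stopifnot(inherits(phys, "physical_params"))
  if (!is.finite(ec50) || ec50 <= 0) stop("`ec50` must be > 0")
  gradient_shape(lambda = phys$decay_length, C = phys$c_far / ec50)
}

#' Hill dose-response parameters for one readout channel
#'
#' @param n Hill coefficient, integer in 1..7. The gene-expression channel
#'   (P_FUS1 promoter output) is non-cooperative and uses `n = 1`; the
#'   switch-like morphological channel uses a fitted integer.
#' @param A response amplitude, > 0 (a.u. for fluorescence, um for length).
#' @param b baseline, same units as `A`.
#' @return An object of class `response_params`.
#' @examples
#' response_params(n = 3, A = 25, b = 5)   # morphology channel
#' @export
response_params <- function(n, A, b) {
  if (length(n) != 1 || !is.finite(n) || n != round(n) || n < 1 || n > 7)
    stop("`n` must be a single integer in 1..7")
  if (!is.finite(A) || A <= 0) stop("`A` must be > 0")
  if (!is.finite(b)) stop("`b` must be finite")
  structure(list(n = as.integer(n), A = A, b = b), class = "response_params")
}

#' @export
print.response_params <- function(x, ...) {
  cat(sprintf("Response: n = %d, A = %.4g, b = %.4g\n", x$n, x$A, x$b))
  invisible(x)
}
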