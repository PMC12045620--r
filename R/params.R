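#' Physical model parameters for a dipolar active Brownian swimmer
#'
#' Bundles the physical constants describing one magnetotactic swimmer and its
#' environment: particle diameter, magnetic moment, self-propulsion speed,
#' temperature, viscosity, the strength of the repulsive surface force, the
#' surface-torque length, and the applied magnetic field.
#'
#' @param sigma Particle diameter, micrometres.
#' @param mu Magnetic moment, J/T.
#' @param v0 Self-propulsion speed, micrometres per second.
#' @param T Temperature, Kelvin.
#' @param eta Dynamic viscosity, Pa s.
#' @param eps Surface-force strength, in multiples of kB*T.
#' @param alpha Surface-torque length, micrometres.
#' @param B Magnetic field magnitude, Tesla.
#' @param field_dir Unit 2-vector giving the field direction (defaults to +x,
#'   the direction of the channel exit).
#'
#' @details Defaults are the measured parameters of \emph{Magnetospirillum
#'   gryphiswaldense} MSR-1: a 1 micrometre body, magnetic moment 4e-16 J/T,
#'   swimming speed 50 um/s, water at 298 K, a WCA repulsion of strength
#'   4 kB*T and a surface-torque length of 0.2 um.
#'
#' @return An object of class \code{"magswim_params"}: a list with the fields
#'   above.
#' @examples
#' p <- model_params()
#' derive_coefficients(p)
#' @export
model_params <- function(sigma = 1, mu = 4e-16, v0 = 50, T = 298,
                         eta = 8.9e-4, eps = 4, alpha = 0.2,
                         B = 50e-6, field_dir = c(1, 0)) {
  scalars <- c(sigma = sigma, mu = mu, v0 = v0, T = T, eta = eta, eps = eps)
  if (any(!is.finite(scalars)) || any(scalars <= 0))
    stop("sigma, mu, v0, T, eta and eps must all be positive and finite")
  if (!is.finite(B) || B < 0) stop("B must be >= 0")
  if (!is.finite(alpha) || alpha < 0) stop("alpha must be >= 0")
  nd <- sqrt(sum(field_dir^2))
  if (length(field_dir) != 2L || nd == 0) stop("field_dir must be a nonzero 2-vector")
  structure(list(sigma = sigma, mu = mu, v0 = v0, T = T, eta = eta,
                 eps = eps, alpha = alpha, B = B,
                 field_dir = field_dir / nd),
            class = "magswim_params")
}

#' @export
print.magswim_params <- function(x, ...) {
  cat("Dipolar active Brownian swimmer parameters\n")
  cat(sprintf("  sigma = %g um, v0 = %g um/s, mu = %g J/T\n", x$sigma, x$v0, x$mu))
  cat(sprintf("  T = %g K, eta = %g Pa s, eps = %g kBT, alpha = %g um\n",
              x$T, x$eta, x$eps, x$alpha))
  cat(sprintf("  B = %g uT along (%.3g, %.3g)\n", x$B * 1e6,
              x$field_dir[1], x$field_dir[2]))
  invisible(x)
}

#' Boltzmann constant, J/K
#' @keywords internal
.kB <- 1.380649e-23

#' Drag and diffusion coefficients from physical parameters
#'
#' Stokes drag for a sphere of diameter sigma: translational drag
#' gammaT = 3 pi eta sigma and rotational drag gammaR = pi eta sigma^3, with
#' diffusion coefficients fixed by fluctuation-dissipation, DT = kB*T/gammaT
#' and DR = kB*T/gammaR.
#'
#' @param params A \code{\link{model_params}} object.
#' @return A list of class \code{"magswim_coeffs"} with \code{kBT} (J),
#'   \code{gammaT} (kg/s), \code{gammaR} (N m s), \code{DT} (um^2/s) and
#'   \code{DR} (rad^2/s).
#' @examples
#' derive_coefficients(model_params())$DT  # ~0.49 um^2/s
#' @export
derive_coefficients <- function(params) {
  stopifnot(inherits(params, "magswim_params"))
  sigma_m <- params$sigma * 1e-6
  kBT <- .kB * params$T
  gammaT <- 3 * pi * params$eta * sigma_m
  gammaR <- pi * params$eta * sigma_m^3
  structure(list(kBT = kBT, gammaT = gammaT, gammaR = gammaR,
                 DT = kBT / gammaT * 1e12,   # m^2/s -> um^2/s
                 DR = kBT / gammaR),
            class = "magswim_coeffs")
}

#' @export
print.magswim_coeffs <- function(x, ...) {
  cat(sprintf("kBT = %.4g J, gammaT = %.4g kg/s, gammaR = %.4g N m s\n",
              x$kBT, x$gammaT, x$gammaR))
  cat(sprintf("DT = %.4g um^2/s, DR = %.4g rad^2/s\n", x$DT, x$DR))
  invisible(x)
}

#' Reduced (dimensionless) units of the swimmer model
#'
#' Lengths are measured in particle diameters sigma and times in sigma^2/DT.
#' The field is referred to B0 = 1e-5 T (the order of magnitude of the
#' geomagnetic field), the dipole strength to mu* = mu*B0/kBT, the force
#' strength to eps* = eps/kBT, and the reduced self-propulsion speed
#' v0*sigma/DT equals the Peclet number.
#'
#' @param params A \code{\link{model_params}} object.
#' @param coeffs Optional \code{\link{derive_coefficients}} result.
#' @return A list of class \code{"magswim_reduced"} with \code{length_scale}
#'   (um), \code{time_scale} (s), \code{B0} (T), \code{B_star},
#'   \code{mu_star}, \code{eps_star} and \code{peclet}.
#' @examples
#' to_reduced(model_params())$peclet  # ~102
#' @export
to_reduced <- function(params, coeffs = derive_coefficients(params)) {
  structure(list(length_scale = params$sigma,
                 time_scale = params$sigma^2 / coeffs$DT,
                 B0 = 1e-5,
                 B_star = params$B / 1e-5,
                 mu_star = params$mu * 1e-5 / coeffs$kBT,
                 eps_star = params$eps,
                 peclet = params$v0 * params$sigma / coeffs$DT),
            class = "magswim_reduced")
}

#' Convert a reduced time/length back to physical units
#'
#' Round-trip helpers used mainly in tests: physical -> reduced -> physical is
#' the identity up to floating point.
#'
#' @param reduced A \code{\link{to_reduced}} result.
#' @param t_star,r_star Reduced time / length values.
#' @return Physical seconds / micrometres.
#' @export
from_reduced_time <- function(reduced, t_star) t_star * reduced$time_scale

#' @rdname from_reduced_time
#' @export
from_reduced_length <- function(reduced, r_star) r_star * reduced$length_scale
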