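#' WCA cutoff distance
#'
#' The repulsive surface force vanishes at centre-to-centre distances
#' \code{|rS| >= 2^(1/6) sigma}.
#' @param sigma Particle diameter, micrometres.
#' @return Cutoff, micrometres.
#' @export
wca_cutoff <- function(sigma = 1) 2^(1 / 6) * sigma

#' Repulsive surface force between particle and virtual particle
#'
#' Weeks-Chandler-Andersen force between the swimmer and a virtual particle
#' whose surface sits at the nearest point of the solid:
#' \deqn{F_S = 48 \epsilon \frac{\vec r_S}{r_S^2}
#'   \left[(\sigma/r_S)^{12} - \tfrac12 (\sigma/r_S)^6\right]}
#' for \code{|rS| < 2^(1/6) sigma}, and exactly zero beyond.
#'
#' @param rS 2-vector from the virtual-particle centre to the particle centre,
#'   micrometres.
#' @param eps Force strength, Joules (pass \code{eps_kBT * kBT}).
#' @param sigma Particle diameter, micrometres.
#' @return Force 2-vector, Newtons.
#' @examples
#' co <- derive_coefficients(model_params())
#' surface_force(c(1, 0), eps = 4 * co$kBT, sigma = 1)  # |F| = 24 eps / sigma
#' @export
surface_force <- function(rS, eps, sigma) {
  r <- sqrt(sum(rS^2))
  if (r <= 0) stop("|rS| must be positive")
  if (r < 0.3 * sigma)
    stop("stiff overlap: |rS| < 0.3 sigma (time step too large?)")
  if (r >= wca_cutoff(sigma)) return(c(0, 0))
  s6 <- (sigma / r)^6
  # rS in um: the 1/rS^2 prefactor carries one inverse length -> convert to m
  48 * eps * rS / (r * 1e-6 * r) * (s6 * s6 - 0.5 * s6)
}

#' Aligning torque of the external magnetic field
#'
#' The dipole moment is locked to the body axis, so a homogeneous field exerts
#' no force but a restoring torque of magnitude \code{mu B |sin(phi_rel)|}
#' that rotates the orientation towards the field direction: the contribution
#' to \code{dphi/dt} is \code{-(mu B / gammaR) sin(phi_rel)} with
#' \code{phi_rel} the angle from the field to the body axis.
#'
#' @param phi_rel Angle from field direction to orientation, radians.
#' @param B Field magnitude, Tesla.
#' @param mu Magnetic moment, J/T.
#' @return Signed torque (z-component), N m. Zero at \code{phi_rel = 0}
#'   (stable) and \code{phi_rel = pi} (unstable).
#' @examples
#' magnetic_torque(pi / 2, B = 50e-6, mu = 4e-16)  # -2e-20 N m
#' @export
magnetic_torque <- function(phi_rel, B, mu) -mu * B * sin(phi_rel)

#' Surface torque near an obstacle or wall
#'
#' Phenomenological reorientation torque of strength set by the length
#' \code{alpha}: \deqn{\tau_S = \alpha [\hat e \times F_S]_z} It rotates the
#' swimming direction towards the outward surface normal, modelling the
#' steric/hydrodynamic realignment observed when bacteria slide along walls.
#'
#' @param e_hat Unit orientation 2-vector.
#' @param FS Surface force 2-vector, Newtons.
#' @param alpha Surface-torque length, micrometres.
#' @return Signed torque (z-component), N m.
#' @examples
#' surface_torque(c(1, 0), c(0, 1e-13), alpha = 0.2)
#' @export
surface_torque <- function(e_hat, FS, alpha)
  alpha * 1e-6 * (e_hat[1] * FS[2] - e_hat[2] * FS[1])
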