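#' Ensemble state of the particle swarm
#'
#' @param positions N x 2 matrix of positions, micrometres.
#' @param angles N orientation angles phi (radians); the body axis is
#'   \code{(cos(phi), sin(phi))}. Wrapped to (-pi, pi].
#' @param time Time stamp, seconds.
#' @return List of class \code{"ensemble_state"}.
#' @export
ensemble_state <- function(positions, angles, time = 0) {
  positions <- matrix(as.numeric(positions), ncol = 2)
  if (nrow(positions) != length(angles))
    stop("positions and angles disagree in length")
  structure(list(time = time, positions = positions,
                 angles = wrap_angle(as.numeric(angles))),
            class = "ensemble_state")
}

#' Wrap angles to (-pi, pi]
#' @param phi Angles, radians.
#' @return Wrapped angles.
#' @export
wrap_angle <- function(phi) {
  out <- phi - 2 * pi * floor((phi + pi) / (2 * pi))
  out[out <= -pi] <- pi
  out
}

#' One Euler-Maruyama step of the swimmer equations of motion (reference path)
#'
#' Pure-R, vectorised update of the overdamped equations of motion: the
#' position advances by self-propulsion, the mobility-scaled surface force of
#' the single nearest contact, and translational noise; the angle advances by
#' the magnetic and surface torques over the rotational drag plus rotational
#' noise. All particles are updated simultaneously from the pre-step state.
#' Long simulations use the compiled engine in \code{\link{run_simulation}};
#' this function defines the update rule and backs the oracle tests.
#'
#' @param state An \code{\link{ensemble_state}}.
#' @param geometry A \code{\link{channel_geometry}}.
#' @param params A \code{\link{model_params}}.
#' @param coeffs Optional \code{\link{derive_coefficients}} result.
#' @param dt Time step, seconds.
#' @param noise Either \code{NULL} (draw from R's RNG), \code{"none"}
#'   (deterministic step), or a list with an N x 2 matrix \code{trans} and an
#'   N-vector \code{rot} of standard-normal draws.
#' @return The advanced \code{ensemble_state}.
#' @examples
#' st <- ensemble_state(cbind(0, 0), 0)
#' g <- channel_geometry(100, 100, walls = character(0))
#' em_step(st, g, model_params(), dt = 1e-4, noise = "none")
#' @export
em_step <- function(state, geometry, params, coeffs = derive_coefficients(params),
                    dt, noise = NULL) {
  stopifnot(dt > 0)
  n <- nrow(state$positions)
  if (is.null(noise)) {
    noise <- list(trans = matrix(stats::rnorm(2 * n), ncol = 2),
                  rot = stats::rnorm(n))
  } else if (identical(noise, "none")) {
    noise <- list(trans = matrix(0, n, 2), rot = numeric(n))
  }
  phi_field <- atan2(params$field_dir[2], params$field_dir[1])
  eps_J <- params$eps * coeffs$kBT
  pos <- state$positions
  phi <- state$angles
  new_pos <- pos
  new_phi <- phi
  for (i in seq_len(n)) {
    e_hat <- c(cos(phi[i]), sin(phi[i]))
    FS <- c(0, 0)
    ct <- nearest_surface_contact(pos[i, ], geometry, params$sigma,
                                  range = wca_cutoff(params$sigma))
    if (!is.null(ct)) FS <- surface_force(ct$rS, eps_J, params$sigma)
    tau <- magnetic_torque(phi[i] - phi_field, params$B, params$mu) +
      surface_torque(e_hat, FS, params$alpha)
    v <- params$v0 * e_hat + FS / coeffs$gammaT * 1e6    # um/s
    new_pos[i, ] <- pos[i, ] + v * dt +
      sqrt(2 * coeffs$DT * dt) * noise$trans[i, ]
    new_phi[i] <- phi[i] + tau / coeffs$gammaR * dt +
      sqrt(2 * coeffs$DR * dt) * noise$rot[i]
  }
  ensemble_state(new_pos, new_phi, time = state$time + dt)
}
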