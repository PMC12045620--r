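#' Simulation configuration
#'
#' @param dt Integration time step, seconds. The engine additionally refines
#'   steps near surfaces (see the package vignette).
#' @param duration Total simulated time, seconds.
#' @param seed Integer RNG seed for the simulation's noise stream.
#' @param sample_interval Seconds between stored frames.
#' @param field_schedule Piecewise-constant field magnitude: a data.frame with
#'   columns \code{t} (segment start, seconds, first must be 0) and \code{B}
#'   (Tesla), or \code{NULL} to hold the field of \code{params} constant.
#' @return List of class \code{"simulation_config"}.
#' @export
simulation_config <- function(dt = 1e-4, duration, seed = 1,
                              sample_interval = 1, field_schedule = NULL) {
  stopifnot(dt > 0, duration >= 0)
  if (duration > 0 && !(dt <= sample_interval && sample_interval <= duration))
    stop("need dt <= sample_interval <= duration")
  if (!is.null(field_schedule)) {
    field_schedule <- as.data.frame(field_schedule)
    stopifnot(all(c("t", "B") %in% names(field_schedule)),
              field_schedule$t[1] == 0,
              !is.unsorted(field_schedule$t))
  }
  structure(list(dt = dt, duration = duration, seed = as.integer(seed),
                 sample_interval = sample_interval,
                 field_schedule = field_schedule),
            class = "simulation_config")
}

#' Run a particle simulation over an obstacle geometry
#'
#' Integrates the ensemble with the compiled Euler-Maruyama engine and returns
#' the sampled trajectory. The field points along +x (towards the exit).
#'
#' @param initial An \code{\link{ensemble_state}} (all particles in fluid).
#' @param geometry A \code{\link{channel_geometry}}.
#' @param params A \code{\link{model_params}} (field direction must be +x).
#' @param config A \code{\link{simulation_config}}.
#' @param stop Stopping rule: \code{"none"}; \code{"arrival"} (freeze a
#'   particle once x >= \code{geometry$exit_x} and record the time);
#'   \code{"escape"} (freeze once x >= \code{x_stop} while clear of every
#'   obstacle's interaction band); or \code{"escape_radial"} (freeze once
#'   farther than \code{x_stop} from \code{stop_center}, again clear of
#'   all interaction bands).
#' @param x_stop Arrival/escape plane, or escape radius, micrometres.
#' @param stop_center Centre (2-vector) of the radial escape criterion.
#' @param record_frames Store sampled frames (set \code{FALSE} for long runs
#'   where only stop times matter).
#' @param all_contacts If TRUE, every solid element within the WCA cutoff
#'   exerts force and torque simultaneously (relevant in wedge apices where
#'   two pillars touch the swimmer at once); the default uses only the
#'   single nearest contact.
#' @return Object of class \code{"abp_trajectory"}: list with \code{frame_t},
#'   \code{x}, \code{y}, \code{phi} (N x frames matrices), \code{final}
#'   (ensemble_state), \code{stop_time} (per particle, NA if never stopped),
#'   \code{n_reject} (rejected elementary moves), \code{min_h} (smallest
#'   surface distance seen), plus geometry/params/config references.
#' @export
run_simulation <- function(initial, geometry, params, config,
                           stop = c("none", "arrival", "escape",
                                    "escape_radial"),
                           x_stop = geometry$exit_x, stop_center = c(0, 0),
                           record_frames = TRUE, all_contacts = FALSE) {
  stop <- match.arg(stop)
  stopifnot(inherits(initial, "ensemble_state"),
            inherits(geometry, "channel_geometry"),
            inherits(params, "magswim_params"),
            inherits(config, "simulation_config"))
  if (max(abs(params$field_dir - c(1, 0))) > 1e-12)
    stop("the compiled engine assumes the field points along +x")
  co <- derive_coefficients(params)
  sched <- config$field_schedule
  if (is.null(sched)) sched <- data.frame(t = 0, B = params$B)
  n <- nrow(initial$positions)

  if (config$duration <= 0 || n == 0) {
    res <- list(x = initial$positions[, 1], y = initial$positions[, 2],
                phi = initial$angles, stop_time = rep(NA_real_, n),
                frame_t = 0,
                FX = matrix(initial$positions[, 1], ncol = 1),
                FY = matrix(initial$positions[, 2], ncol = 1),
                FPHI = matrix(initial$angles, ncol = 1),
                n_reject = 0, min_h = Inf)
  } else {
    res <- .abp_run_cpp(initial$positions[, 1], initial$positions[, 2],
                        initial$angles,
                        geometry$obstacles$x, geometry$obstacles$y,
                        geometry$obstacles$r,
                        .wall_matrix(geometry, params$sigma),
                        params$sigma, params$v0, params$eps * co$kBT,
                        params$mu, params$alpha, co$gammaT, co$gammaR,
                        co$DT, co$DR,
                        sched$t, sched$B,
                        config$dt, config$duration, config$sample_interval,
                        config$seed %% 2^31,
                        switch(stop, none = 0L, arrival = 1L, escape = 2L,
                               escape_radial = 3L),
                        x_stop, stop_center[1], stop_center[2], record_frames,
                        all_contacts)
  }
  structure(list(frame_t = res$frame_t, x = res$FX, y = res$FY, phi = res$FPHI,
                 initial = initial,
                 final = ensemble_state(cbind(res$x, res$y), res$phi,
                                        time = config$duration),
                 stop_time = res$stop_time, n_reject = res$n_reject,
                 min_h = res$min_h, geometry = geometry, params = params,
                 config = config, stop_rule = stop),
            class = "abp_trajectory")
}

#' @export
print.abp_trajectory <- function(x, ...) {
  n <- nrow(x$final$positions)
  cat(sprintf("ABP trajectory: %d particles, %d frames over %g s (dt = %g s)\n",
              n, length(x$frame_t), x$config$duration, x$config$dt))
  ns <- sum(!is.na(x$stop_time))
  if (x$stop_rule != "none")
    cat(sprintf("  stop rule '%s': %d/%d particles stopped\n", x$stop_rule, ns, n))
  if (x$n_reject > 0)
    cat(sprintf("  rejected elementary moves: %g\n", x$n_reject))
  invisible(x)
}

#' @export
as.data.frame.abp_trajectory <- function(x, ...) {
  n <- nrow(x$x); f <- length(x$frame_t)
  data.frame(particle_id = rep(seq_len(n), f),
             t_s = rep(x$frame_t, each = n),
             x_um = as.vector(x$x), y_um = as.vector(x$y),
             phi_rad = as.vector(x$phi))
}

#' Export a trajectory as CSV
#'
#' Long format with columns \code{particle_id, t_s, x_um, y_um, phi_rad}.
#' @param traj An \code{"abp_trajectory"}.
#' @param path Output file.
#' @return \code{path}, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}

#' @export
plot.abp_trajectory <- function(x, max_particles = 50, ...) {
  plot(x$geometry, main = "trajectories")
  n <- min(nrow(x$x), max_particles)
  cols <- grDevices::hcl.colors(n, "Dark 3")
  for (i in seq_len(n))
    graphics::lines(x$x[i, ], x$y[i, ], col = cols[i], lwd = 0.6)
  invisible(x)
}
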