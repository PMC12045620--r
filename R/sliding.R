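#' Extract sliding events along obstacle surfaces from a trajectory
#'
#' A sliding event is a maximal contiguous run of frames during which a
#' particle stays within \code{sliding_band} of one obstacle's surface; the
#' event is kept only if the particle also reaches the interaction band
#' (where the repulsive force acts, h <= 2^(1/6) sigma - sigma/2, about
#' 0.62 um for a 1 um swimmer). The sliding distance is the arc length
#' covered tangentially to the surface: per frame pair, the displacement
#' component perpendicular to the surface normal at the segment midpoint.
#'
#' @param traj An \code{"abp_trajectory"}, finely sampled (<= 0.1 s).
#' @param geometry Geometry with the obstacles (default: the trajectory's).
#' @param sliding_band Band width from the surface, micrometres.
#' @param interaction_band Interaction-band width from the surface.
#' @return data.frame with one row per event: \code{particle_id},
#'   \code{obstacle_id}, \code{t_in_s}, \code{t_out_s}, \code{slide_um},
#'   \code{min_h_um}.
#' @export
detect_sliding_events <- function(traj, geometry = traj$geometry,
                                  sliding_band = 2,
                                  interaction_band =
                                    wca_cutoff(traj$params$sigma) -
                                    traj$params$sigma / 2) {
  ob <- geometry$obstacles
  out <- list()
  if (!nrow(ob)) return(.empty_events())
  tt <- traj$frame_t
  for (i in seq_len(nrow(traj$x))) {
    xs <- traj$x[i, ]; ys <- traj$y[i, ]
    # surface distance to each obstacle at every frame; nearest one counts
    H <- matrix(Inf, length(xs), nrow(ob))
    for (k in seq_len(nrow(ob)))
      H[, k] <- sqrt((xs - ob$x[k])^2 + (ys - ob$y[k])^2) - ob$r[k]
    near_k <- max.col(-H)
    near_h <- H[cbind(seq_along(xs), near_k)]
    in_band <- near_h <= sliding_band
    if (!any(in_band)) next
    r <- rle(in_band & c(TRUE, diff(near_k) == 0L))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    # contiguous in-band runs on a single obstacle
    runs <- which(r$values)
    for (j in runs) {
      s <- starts[j]; e <- ends[j]
      if (s > 1 && in_band[s - 1] && near_k[s - 1] == near_k[s]) s <- s - 1
      k <- near_k[e]
      if (min(near_h[s:e]) > interaction_band) next
      slide <- 0
      if (e > s) {
        for (f in s:(e - 1)) {
          dx <- xs[f + 1] - xs[f]; dy <- ys[f + 1] - ys[f]
          mx <- (xs[f + 1] + xs[f]) / 2 - ob$x[k]
          my <- (ys[f + 1] + ys[f]) / 2 - ob$y[k]
          nm <- sqrt(mx^2 + my^2)
          if (nm == 0) next
          nrm <- (dx * mx + dy * my) / nm
          slide <- slide + sqrt(max(0, dx^2 + dy^2 - nrm^2))
        }
      }
      out[[length(out) + 1L]] <- data.frame(
        particle_id = i, obstacle_id = k, t_in_s = tt[s], t_out_s = tt[e],
        slide_um = slide, min_h_um = min(near_h[s:e]))
    }
  }
  if (!length(out)) return(.empty_events())
  do.call(rbind, out)
}

.empty_events <- function()
  data.frame(particle_id = integer(0), obstacle_id = integer(0),
             t_in_s = numeric(0), t_out_s = numeric(0),
             slide_um = numeric(0), min_h_um = numeric(0))

#' Normalised histogram of sliding distances
#'
#' @param events Event table from \code{\link{detect_sliding_events}} (>= 1
#'   row).
#' @param bin_edges Bin edges, micrometres; default 0 to 30 in 2 um bins.
#'   Distances beyond the last edge are pooled into the final bin.
#' @return data.frame \code{mid}, \code{freq} with \code{sum(freq) == 1}.
#' @examples
#' ev <- data.frame(slide_um = c(1, 1, 3))
#' sliding_histogram(ev, bin_edges = 0:4)
#' @export
sliding_histogram <- function(events, bin_edges = seq(0, 30, by = 2)) {
  if (nrow(events) == 0) stop("no sliding events to histogram")
  d <- pmin(events$slide_um, max(bin_edges) - 1e-9)
  counts <- graphics::hist(d, breaks = bin_edges, plot = FALSE)$counts
  data.frame(mid = (bin_edges[-1] + bin_edges[-length(bin_edges)]) / 2,
             freq = counts / sum(counts))
}

# default sliding test-bed: one pillar in a walled box, particles scattered
# in the fluid with random headings, no magnetic field
.sliding_testbed <- function(r_obstacle = 50, box = 220) {
  channel_geometry(box, box,
                   data.frame(x = box / 2, y = box / 2, r = r_obstacle),
                   walls = c("left", "bottom", "top"))
}

#' Simulate sliding statistics for one surface-torque length
#'
#' Scatters particles around a single pillar at zero field, runs the engine,
#' and extracts the sliding-distance events. Used by
#' \code{\link{calibrate_alpha}} and the sliding property tests.
#'
#' @param alpha Surface-torque length, micrometres.
#' @param n_particles,duration Ensemble size and simulated seconds.
#' @param seed Integer seed.
#' @param params Base parameters (B is forced to 0, alpha overridden).
#' @param geometry Optional geometry; default one 50 um pillar in a box.
#' @param sample_interval Frame spacing, seconds.
#' @return Event table (see \code{\link{detect_sliding_events}}).
#' @export
simulate_sliding_events <- function(alpha, n_particles = 50, duration = 40,
                                    seed = 1, params = model_params(),
                                    geometry = .sliding_testbed(),
                                    sample_interval = 0.05) {
  p <- params
  p$alpha <- alpha
  p$B <- 0
  set.seed(seed)
  pos <- matrix(NA_real_, n_particles, 2)
  filled <- 0
  while (filled < n_particles) {
    cand <- cbind(stats::runif(2 * n_particles, 2, geometry$length - 2),
                  stats::runif(2 * n_particles, 2, geometry$width - 2))
    ob <- geometry$obstacles
    ok <- rep(TRUE, nrow(cand))
    for (k in seq_len(nrow(ob)))
      ok <- ok & ((cand[, 1] - ob$x[k])^2 + (cand[, 2] - ob$y[k])^2 >
                    (ob$r[k] + 1)^2)
    cand <- cand[ok, , drop = FALSE]
    take <- min(nrow(cand), n_particles - filled)
    if (take > 0) pos[filled + seq_len(take), ] <- cand[seq_len(take), ]
    filled <- filled + take
  }
  init <- ensemble_state(pos, stats::runif(n_particles, -pi, pi))
  cfg <- simulation_config(dt = 1e-4, duration = duration, seed = seed + 7L,
                           sample_interval = sample_interval)
  traj <- run_simulation(init, geometry, p, cfg)
  detect_sliding_events(traj, geometry)
}

#' Calibrate the surface-torque length from a sliding-distance histogram
#'
#' For each candidate alpha, sliding distances are simulated at zero field
#' and histogrammed with the same bins as the reference; the calibration
#' objective is the sum of squared frequency differences and the calibrated
#' alpha is its arg-min on the grid.
#'
#' @param reference_hist data.frame \code{mid, freq} (e.g. from
#'   \code{\link{sliding_histogram}}) against which to match.
#' @param alpha_grid Candidate surface-torque lengths, micrometres.
#' @param bin_edges Bin edges matching \code{reference_hist}.
#' @param n_particles,duration,seed,params,geometry Passed to
#'   \code{\link{simulate_sliding_events}}.
#' @return Object of class \code{"alpha_calibration"}: \code{alpha_grid},
#'   \code{objective}, \code{alpha_star}, \code{n_events} per alpha.
#' @export
calibrate_alpha <- function(reference_hist,
                            alpha_grid = c(0.05, 0.1, 0.2, 0.4, 0.8),
                            bin_edges = seq(0, 30, by = 2),
                            n_particles = 50, duration = 40, seed = 1,
                            params = model_params(),
                            geometry = .sliding_testbed()) {
  stopifnot(length(alpha_grid) >= 1)
  objective <- n_events <- numeric(length(alpha_grid))
  for (k in seq_along(alpha_grid)) {
    ev <- simulate_sliding_events(alpha_grid[k], n_particles, duration,
                                  seed = seed + 31L * k, params = params,
                                  geometry = geometry)
    n_events[k] <- nrow(ev)
    if (nrow(ev) == 0) { objective[k] <- Inf; next }
    h <- sliding_histogram(ev, bin_edges)
    objective[k] <- sum((h$freq - reference_hist$freq)^2)
  }
  structure(list(alpha_grid = alpha_grid, objective = objective,
                 alpha_star = alpha_grid[which.min(objective)],
                 n_events = n_events),
            class = "alpha_calibration")
}

#' @export
print.alpha_calibration <- function(x, ...) {
  cat("Surface-torque calibration (squared-frequency objective)\n")
  print(data.frame(alpha_um = x$alpha_grid, objective = x$objective,
                   n_events = x$n_events), row.names = FALSE)
  cat(sprintf("  alpha* = %g um\n", x$alpha_star))
  invisible(x)
}

#' @export
coef.alpha_calibration <- function(object, ...) c(alpha = object$alpha_star)

#' @export
plot.alpha_calibration <- function(x, ...) {
  graphics::plot(x$alpha_grid, x$objective, log = "x", type = "b", pch = 16,
                 xlab = expression(alpha ~ "[um]"), ylab = "objective", ...)
  graphics::abline(v = x$alpha_star, lty = 2)
  invisible(x)
}
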