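#' Seed particles on the entrance line of a channel
#'
#' All particles start at x = \code{geometry$entrance_x}; their y positions
#' are drawn uniformly over the fluid portion of the entrance line (rejection
#' sampling against the obstacles) and orientations are uniform on (-pi, pi].
#'
#' @param n Number of particles.
#' @param geometry A \code{\link{channel_geometry}}.
#' @param seed Integer seed.
#' @param margin Keep-out distance from the y walls, micrometres.
#' @return An \code{\link{ensemble_state}} at time 0.
#' @export
seed_entrance <- function(n, geometry, seed = 1, margin = 1) {
  stopifnot(n >= 0)
  if (n == 0) return(ensemble_state(matrix(numeric(0), 0, 2), numeric(0)))
  set.seed(seed)
  x0 <- geometry$entrance_x
  ob <- geometry$obstacles
  ys <- numeric(0)
  for (tries in 1:1000) {
    cand <- stats::runif(4 * n, margin, geometry$width - margin)
    if (nrow(ob)) {
      near <- which(abs(ob$x - x0) < ob$r + 1)
      if (length(near)) {
        ok <- rep(TRUE, length(cand))
        for (k in near)
          ok <- ok & ((x0 - ob$x[k])^2 + (cand - ob$y[k])^2 > (ob$r[k] + 0.5)^2)
        cand <- cand[ok]
      }
    }
    ys <- c(ys, cand)
    if (length(ys) >= n) break
  }
  if (length(ys) < n) stop("entrance line is (almost) fully blocked")
  ensemble_state(cbind(rep(x0, n), ys[seq_len(n)]),
                 stats::runif(n, -pi, pi))
}

#' Arrival times from a sampled trajectory
#'
#' Per particle, the time of the first stored frame with x >= \code{x_exit};
#' NA (censored) if the particle never crosses. When the trajectory was run
#' with \code{stop = "arrival"}, the engine's step-resolution stop times are
#' returned instead.
#'
#' @param traj An \code{"abp_trajectory"}.
#' @param x_exit Arrival threshold, micrometres.
#' @return Numeric vector of arrival times (s), NA when censored.
#' @export
detect_arrivals <- function(traj, x_exit = traj$geometry$exit_x) {
  if (identical(traj$stop_rule, "arrival") && x_exit == traj$geometry$exit_x) {
    at <- traj$stop_time
    # particles seeded at/past the exit stop during the first step; report 0
    at[traj$initial$positions[, 1] >= x_exit] <- 0
    return(at)
  }
  crossed <- traj$x >= x_exit
  apply(crossed, 1, function(row) {
    i <- which(row)[1]
    if (is.na(i)) NA_real_ else traj$frame_t[i]
  })
}

#' Cumulative arrival curve, first-arrival time and total arrival fraction
#'
#' @param arrival_times Per-particle arrival times, NA = censored.
#' @param n Ensemble size (>= 1).
#' @param duration End of observation, seconds.
#' @param grid Time grid on which to tabulate phi(t); defaults to 200 points.
#' @return Object of class \code{"transit_result"}: \code{phi_of_t}
#'   (data.frame t, phi), \code{t_first} (NA if none arrived), \code{phi_tot},
#'   \code{arrival_times}, \code{n}.
#' @examples
#' arrival_curves(c(10, 20, NA, NA), n = 4, duration = 30)$phi_tot  # 0.5
#' @export
arrival_curves <- function(arrival_times, n = length(arrival_times), duration,
                           grid = NULL) {
  stopifnot(n >= 1)
  at <- arrival_times[!is.na(arrival_times) & arrival_times <= duration]
  if (is.null(grid)) grid <- seq(0, duration, length.out = 200)
  phi <- vapply(grid, function(t) sum(at <= t) / n, numeric(1))
  structure(list(phi_of_t = data.frame(t = grid, phi = phi),
                 t_first = if (length(at)) min(at) else NA_real_,
                 phi_tot = length(at) / n,
                 arrival_times = arrival_times, n = n,
                 duration = duration),
            class = "transit_result")
}

#' @export
print.transit_result <- function(x, ...) {
  cat(sprintf("Transit result: n = %d, phi_tot = %.3f, t_first = %s s\n",
              x$n, x$phi_tot,
              if (is.na(x$t_first)) "NA" else sprintf("%.1f", x$t_first)))
  invisible(x)
}

#' @export
plot.transit_result <- function(x, ...) {
  graphics::plot(x$phi_of_t$t, x$phi_of_t$phi, type = "s",
                 xlab = "t [s]", ylab = expression(phi(t)), ylim = c(0, 1), ...)
  if (!is.na(x$t_first)) graphics::points(x$t_first, 1 / x$n, pch = 1, col = "red3")
  invisible(x)
}

#' Time-summed occupancy heat maps, split by arrival status
#'
#' Every stored frame before a particle's arrival adds one count to the bin
#' holding the particle; the counts of each particle go to the "arrived" or
#' "not arrived" map according to its final status, so the two maps partition
#' the total occupancy.
#'
#' @param traj An \code{"abp_trajectory"}.
#' @param arrival_times From \code{\link{detect_arrivals}}.
#' @param bin Bin size, micrometres.
#' @return List of class \code{"density_maps"} with matrices \code{arrived},
#'   \code{not_arrived}, and \code{bin}.
#' @export
density_heatmaps <- function(traj, arrival_times, bin = 10) {
  stopifnot(bin > 0)
  g <- traj$geometry
  nx <- max(1L, ceiling(g$length / bin))
  ny <- max(1L, ceiling(g$width / bin))
  maps <- list(arrived = matrix(0, nx, ny), not_arrived = matrix(0, nx, ny))
  nt <- length(traj$frame_t)
  for (i in seq_len(nrow(traj$x))) {
    arrived <- !is.na(arrival_times[i])
    keep <- if (arrived) traj$frame_t <= arrival_times[i] else rep(TRUE, nt)
    xi <- pmin(pmax(ceiling(traj$x[i, keep] / bin), 1L), nx)
    yi <- pmin(pmax(ceiling(traj$y[i, keep] / bin), 1L), ny)
    key <- if (arrived) "arrived" else "not_arrived"
    for (f in seq_along(xi))
      maps[[key]][xi[f], yi[f]] <- maps[[key]][xi[f], yi[f]] + 1
  }
  structure(list(arrived = maps$arrived, not_arrived = maps$not_arrived,
                 bin = bin), class = "density_maps")
}

#' @export
plot.density_maps <- function(x, ...) {
  tot <- x$arrived + x$not_arrived
  graphics::image(log1p(t(x$not_arrived)), col = grDevices::hcl.colors(64, "Blues3", rev = TRUE),
                  axes = FALSE, main = "occupancy (blue: not arrived)")
  invisible(x)
}

#' Cumulative OUT:IN throughput ratio
#'
#' Ratio of the summed exit-region counts to the summed entry-region counts
#' over a series of snapshots.
#'
#' @param in_counts,out_counts Equal-length non-negative count series.
#' @return Sum(out)/Sum(in); NaN if the entry sum is zero.
#' @examples
#' throughput_ratio(c(10, 10), c(2, 3))  # 0.25
#' @export
throughput_ratio <- function(in_counts, out_counts) {
  if (length(in_counts) != length(out_counts))
    stop("count series must have equal length")
  if (any(in_counts < 0) || any(out_counts < 0))
    stop("counts must be non-negative")
  sum(out_counts) / sum(in_counts)
}

#' Per-snapshot particle counts in the entry and exit strips
#'
#' @param traj An \code{"abp_trajectory"}.
#' @param strip Width of the IN/OUT regions at the channel ends, micrometres.
#' @return data.frame with columns \code{t}, \code{in_count}, \code{out_count}.
#' @export
region_counts <- function(traj, strip = 200) {
  g <- traj$geometry
  data.frame(t = traj$frame_t,
             in_count = colSums(traj$x <= g$entrance_x + strip),
             out_count = colSums(traj$x >= g$length - strip))
}

#' Transit simulations over a range of field strengths
#'
#' Runs an independent channel-transit simulation per field value on a common
#' geometry (per-value seeds derived deterministically from \code{seed}) and
#' collects the arrival summaries.
#'
#' @param geometry A \code{\link{channel_geometry}}.
#' @param B_values Field magnitudes, Tesla.
#' @param n Particles per run.
#' @param duration Simulated seconds per run.
#' @param seed Base seed.
#' @param params Swimmer parameters (field magnitude is overridden per run).
#' @param dt,sample_interval Passed to \code{\link{simulation_config}}.
#' @return Object of class \code{"field_sweep"}: data.frame \code{summary}
#'   (B_T, n, phi_tot, t_first_s) plus the per-B \code{\link{arrival_curves}}
#'   results.
#' @export
field_sweep <- function(geometry, B_values, n = 100, duration = 600,
                        seed = 1, params = model_params(),
                        dt = 1e-4, sample_interval = 1) {
  stopifnot(length(B_values) >= 1)
  results <- vector("list", length(B_values))
  for (k in seq_along(B_values)) {
    p <- params
    p$B <- B_values[k]
    init <- seed_entrance(n, geometry, seed = seed + 1000L * k)
    cfg <- simulation_config(dt = dt, duration = duration,
                             seed = seed + 1000L * k + 1L,
                             sample_interval = sample_interval)
    traj <- run_simulation(init, geometry, p, cfg, stop = "arrival",
                           record_frames = FALSE)
    results[[k]] <- arrival_curves(detect_arrivals(traj), n = n,
                                   duration = duration)
  }
  structure(list(summary = data.frame(
    B_T = B_values, n = n,
    phi_tot = vapply(results, `[[`, numeric(1), "phi_tot"),
    t_first_s = vapply(results, `[[`, numeric(1), "t_first")),
    results = results), class = "field_sweep")
}

#' @export
print.field_sweep <- function(x, ...) {
  cat("Field sweep of channel transit\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' @export
plot.field_sweep <- function(x, ...) {
  s <- x$summary
  graphics::plot(s$B_T * 1e6, s$phi_tot, log = "", type = "b", pch = 16,
                 xlab = "B [uT]", ylab = expression(phi[tot]), ylim = c(0, 1), ...)
  invisible(x)
}
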