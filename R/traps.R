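#' Two-pillar trap geometry
#'
#' A trap is the concave upstream wedge formed by two overlapping (or
#' touching) circular pillars in a field pointing along +x. The apex is the
#' upstream intersection point of the two circles; the depth d is the
#' upstream excursion along the field axis a field-aligned slider must make
#' from the apex to the release pole (the upstream pole x_c - r of the easier
#' circle): \code{d = x_apex - max_i(x_center_i - r_i)}.
#'
#' @param circle_1,circle_2 Lists/rows with \code{x}, \code{y}, \code{r}.
#' @return Object of class \code{"trap_geometry"} with the circles,
#'   \code{apex} (2-vector) and \code{depth} (micrometres).
#' @export
trap_geometry <- function(circle_1, circle_2) {
  c1 <- as.list(circle_1); c2 <- as.list(circle_2)
  d12 <- sqrt((c1$x - c2$x)^2 + (c1$y - c2$y)^2)
  if (d12 > c1$r + c2$r)
    stop("no trap: circles neither overlap nor touch")
  apex <- .upstream_intersection(c1, c2)
  depth <- apex[1] - max(c1$x - c1$r, c2$x - c2$r)
  structure(list(circle_1 = c1, circle_2 = c2, apex = apex,
                 depth = max(0, depth)),
            class = "trap_geometry")
}

# upstream (smallest-x) intersection point of two circles; for tangent
# circles this is the tangency point
.upstream_intersection <- function(c1, c2) {
  dx <- c2$x - c1$x; dy <- c2$y - c1$y
  d <- sqrt(dx^2 + dy^2)
  if (d == 0) stop("coincident circle centres")
  a <- (c1$r^2 - c2$r^2 + d^2) / (2 * d)
  h2 <- c1$r^2 - a^2
  h <- sqrt(max(0, h2))
  mx <- c1$x + a * dx / d
  my <- c1$y + a * dy / d
  p1 <- c(mx + h * (-dy) / d, my + h * dx / d)
  p2 <- c(mx - h * (-dy) / d, my - h * dx / d)
  if (p1[1] <= p2[1]) p1 else p2
}

#' @export
print.trap_geometry <- function(x, ...) {
  cat(sprintf("Two-pillar trap: r = (%g, %g) um, apex (%.2f, %.2f), depth %.2f um\n",
              x$circle_1$r, x$circle_2$r, x$apex[1], x$apex[2], x$depth))
  invisible(x)
}

#' @export
plot.trap_geometry <- function(x, ...) {
  cs <- rbind(as.data.frame(x$circle_1), as.data.frame(x$circle_2))
  lim <- c(min(cs$x - cs$r), max(cs$x + cs$r))
  graphics::plot(NA, xlim = lim, ylim = range(c(cs$y - cs$r, cs$y + cs$r)),
                 asp = 1, xlab = "x [um]", ylab = "y [um]", ...)
  graphics::symbols(cs$x, cs$y, circles = cs$r, inches = FALSE, add = TRUE,
                    bg = "grey80")
  graphics::points(x$apex[1], x$apex[2], pch = 4, col = "red3")
  invisible(x)
}

#' Symmetric two-pillar trap
#'
#' Equal radii r, centres at (0, +dy/2) and (0, -dy/2). The apex is the
#' upstream intersection \code{(-sqrt(r^2 - (dy/2)^2), 0)} and the depth
#' reduces to \code{r - sqrt(r^2 - (dy/2)^2)}; tangent pillars (dy = 2r) give
#' the deepest symmetric trap, d = r.
#'
#' @param r Pillar radius, micrometres.
#' @param dy Centre separation perpendicular to the field, micrometres;
#'   must satisfy 0 < dy <= 2r.
#' @return A \code{\link{trap_geometry}}.
#' @examples
#' trap_depth(make_symmetric_trap(50, 100))  # 50
#' @export
make_symmetric_trap <- function(r, dy) {
  stopifnot(r > 0)
  if (!(dy > 0 && dy <= 2 * r))
    stop("no trap: need 0 < dy <= 2 r (circles must overlap or touch)")
  trap_geometry(list(x = 0, y = dy / 2, r = r),
                list(x = 0, y = -dy / 2, r = r))
}

#' Trap depth
#' @param trap A \code{\link{trap_geometry}}.
#' @return Depth d, micrometres.
#' @export
trap_depth <- function(trap) trap$depth

#' Centre separation realising a requested symmetric-trap depth
#'
#' Inverts \code{d = r - sqrt(r^2 - (dy/2)^2)}: \code{dy = 2 sqrt(d (2r - d))}.
#' @param r Pillar radius, micrometres.
#' @param d Requested depth, 0 < d <= r.
#' @return dy, micrometres.
#' @export
depth_to_dy <- function(r, d) {
  if (any(d <= 0 | d > r)) stop("depth must satisfy 0 < d <= r")
  2 * sqrt(d * (2 * r - d))
}

#' Random trap from a two-pillar library
#'
#' Pillar radii and the centre offsets parallel and perpendicular to the
#' field are drawn uniformly from the given ranges; draws are rejected until
#' the circles overlap and form a concave upstream wedge of depth > 0.5 um.
#'
#' @param seed Integer seed (deterministic trap per seed).
#' @param r_range Radius range, micrometres.
#' @param dx_range,dy_range Ranges of the centre offsets, micrometres.
#' @param max_tries Rejection bound.
#' @return A \code{\link{trap_geometry}}.
#' @export
sample_random_trap <- function(seed, r_range = c(30, 80),
                               dx_range = c(-40, 40), dy_range = c(20, 150),
                               max_tries = 1000) {
  set.seed(seed)
  for (k in seq_len(max_tries)) {
    r1 <- stats::runif(1, r_range[1], r_range[2])
    r2 <- stats::runif(1, r_range[1], r_range[2])
    dx <- stats::runif(1, dx_range[1], dx_range[2])
    dy <- stats::runif(1, dy_range[1], dy_range[2])
    d12 <- sqrt(dx^2 + dy^2)
    if (d12 >= r1 + r2 || d12 <= abs(r1 - r2)) next
    tr <- trap_geometry(list(x = 0, y = dy / 2, r = r1),
                        list(x = dx, y = -dy / 2, r = r2))
    if (tr$depth > 0.5) return(tr)
  }
  stop("could not sample an overlapping trap within max_tries")
}

# open two-pillar geometry for the engine (no walls)
.trap_channel <- function(trap, pad = 150) {
  cs <- rbind(as.data.frame(trap$circle_1), as.data.frame(trap$circle_2))
  xmin <- min(cs$x - cs$r) - pad
  ymin <- min(cs$y - cs$r) - pad
  # shift so the box is positive; remember the offset
  off <- c(-xmin, -ymin)
  g <- channel_geometry(length = max(cs$x + cs$r) - xmin + pad,
                        width = max(cs$y + cs$r) - ymin + pad,
                        obstacles = data.frame(x = cs$x + off[1],
                                               y = cs$y + off[2], r = cs$r),
                        walls = character(0))
  attr(g, "offset") <- off
  g
}

#' Simulate the escape of swimmers from a trap apex
#'
#' Particles start 1.5 sigma from the apex along the wedge bisector (for a
#' symmetric tangent trap: straight upstream) with uniformly random
#' orientations, and are integrated at the given field until they escape or
#' until the censoring cap. Two escape notions are implemented (see the
#' package vignette): \code{"committed"} -- the swimmer has crossed the
#' plane 2 sigma downstream of the apex while clear of both pillars'
#' interaction bands, i.e. it has left the trap and proceeded downstream --
#' and \code{"barrier"} -- the swimmer is farther from the apex than the
#' farther release pole (plus 2 sigma) and clear of both bands, the
#' barrier-top notion of a Kramers escape, comparable across all field
#' strengths including B = 0. No re-entry check is applied in either case.
#'
#' @param trap A \code{\link{trap_geometry}}.
#' @param params A \code{\link{model_params}} (its B is the escape field).
#' @param n Ensemble size (100 swimmers per trap by convention).
#' @param seed Integer seed.
#' @param t_cap Censoring cap, seconds.
#' @param dt Time step, seconds.
#' @param criterion Escape notion, \code{"committed"} (default) or
#'   \code{"barrier"}; see Details.
#' @param record_frames Keep sampled frames (for plots; off by default).
#' @return Object of class \code{"escape_result"}: \code{escape_times} (NA
#'   when censored), \code{censored}, \code{tau} (censored-MLE exponential
#'   mean, see \code{\link{fit_exponential_mean}}), \code{n_escaped},
#'   \code{t_cap}, and the trajectory when recorded.
#' @export
simulate_escape <- function(trap, params = model_params(), n = 100, seed = 1,
                            t_cap = 600, dt = 1e-4,
                            criterion = c("committed", "barrier"),
                            record_frames = FALSE) {
  criterion <- match.arg(criterion)
  stopifnot(n >= 0)
  if (n == 0)
    return(structure(list(escape_times = numeric(0), censored = logical(0),
                          tau = NA_real_, n_escaped = 0L, t_cap = t_cap),
                     class = "escape_result"))
  g <- .trap_channel(trap)
  off <- attr(g, "offset")
  c1 <- trap$circle_1; c2 <- trap$circle_2
  n1 <- (trap$apex - c(c1$x, c1$y)) / c1$r
  n2 <- (trap$apex - c(c2$x, c2$y)) / c2$r
  bis <- n1 + n2
  if (sqrt(sum(bis^2)) < 1e-8) bis <- c(-1, 0)  # tangent trap: straight upstream
  bis <- bis / sqrt(sum(bis^2))
  start <- trap$apex + 1.5 * params$sigma * bis + off
  init <- ensemble_state(matrix(rep(start, each = n), n, 2),
                         local({ set.seed(seed); stats::runif(n, -pi, pi) }))
  cfg <- simulation_config(dt = dt, duration = t_cap, seed = seed + 13L,
                           sample_interval = min(1, t_cap))
  if (criterion == "barrier") {
    pole_dist <- function(cc)
      sqrt(sum((trap$apex - c(cc$x - cc$r, cc$y))^2))
    r_esc <- max(pole_dist(c1), pole_dist(c2)) + 2 * params$sigma
    traj <- run_simulation(init, g, params, cfg, stop = "escape_radial",
                           x_stop = r_esc, stop_center = trap$apex + off,
                           record_frames = record_frames)
  } else {
    traj <- run_simulation(init, g, params, cfg, stop = "escape",
                           x_stop = trap$apex[1] + off[1] + 2 * params$sigma,
                           record_frames = record_frames)
  }
  et <- traj$stop_time
  cen <- is.na(et)
  structure(list(escape_times = et, censored = cen,
                 tau = if (any(!cen)) fit_exponential_mean(et, cen, t_cap)
                       else NA_real_,
                 n_escaped = sum(!cen), t_cap = t_cap,
                 all_censored = all(cen), criterion = criterion,
                 trajectory = if (record_frames) traj else NULL),
            class = "escape_result")
}

#' @export
print.escape_result <- function(x, ...) {
  cat(sprintf("Trap escape: %d/%d escaped (cap %g s), tau = %s s\n",
              x$n_escaped, length(x$escape_times), x$t_cap,
              if (is.na(x$tau)) "NA" else sprintf("%.1f", x$tau)))
  invisible(x)
}

#' @export
coef.escape_result <- function(object, ...) c(tau = object$tau)

#' @export
plot.escape_result <- function(x, ...) {
  et <- sort(x$escape_times[!x$censored])
  n <- length(x$escape_times)
  surv <- 1 - seq_along(et) / n
  graphics::plot(et, pmax(surv, 0.5 / n), log = "y", type = "s",
                 xlab = "t [s]", ylab = "P(escape time > t)", ...)
  if (!is.na(x$tau)) {
    tau <- x$tau
    graphics::curve(exp(-t / tau), xname = "t", add = TRUE, lty = 2,
                    col = "red3")
  }
  invisible(x)
}

#' Censored maximum-likelihood mean of exponential escape times
#'
#' Right-censored exponential MLE: the sum of all observation times (escapees
#' contribute their escape time, censored particles the cap) divided by the
#' number of uncensored escapes.
#'
#' @param times Observation times; for censored entries pass the cap (NA
#'   entries are replaced by \code{t_cap}).
#' @param censored Logical vector.
#' @param t_cap Cap substituted for NA censored times.
#' @return tau, seconds.
#' @examples
#' fit_exponential_mean(c(1, 2, 3), c(FALSE, FALSE, FALSE))      # 2
#' fit_exponential_mean(c(2, 10), c(FALSE, TRUE))                # 12
#' @export
fit_exponential_mean <- function(times, censored = rep(FALSE, length(times)),
                                 t_cap = NULL) {
  if (!any(!censored)) stop("no uncensored escape times")
  tt <- times
  if (any(is.na(tt))) {
    if (is.null(t_cap)) stop("NA times need t_cap")
    tt[is.na(tt)] <- t_cap
  }
  sum(tt) / sum(!censored)
}

.fit_log_linear <- function(xv, tau) {
  ok <- is.finite(tau) & tau > 0
  if (sum(ok) < 2) return(list(tau0 = NA_real_, scale = NA_real_,
                               r_squared = NA_real_))
  fit <- stats::lm(log(tau[ok]) ~ xv[ok])
  sl <- unname(stats::coef(fit)[2])
  list(tau0 = exp(unname(stats::coef(fit)[1])),
       scale = 1 / sl,
       r_squared = summary(fit)$r.squared)
}

#' Escape-time sweep over field strengths
#'
#' Simulates the escape from one trap at several field magnitudes and fits
#' the Kramers-like exponential law \code{tau = tau0 exp(B / B_bar)} by least
#' squares in log tau.
#'
#' @param trap A \code{\link{trap_geometry}}.
#' @param B_values Field magnitudes, Tesla (>= 1; the fit needs >= 2).
#' @param params Base parameters.
#' @param n Swimmers per field value.
#' @param seed Base seed (per-value seeds derived deterministically).
#' @param t_cap,dt Passed to \code{\link{simulate_escape}}.
#' @param criterion Escape notion; sweeps default to \code{"barrier"}, the
#'   notion comparable across field strengths (see the vignette).
#' @return Object of class \code{"escape_sweep"}: data.frame \code{summary}
#'   (x_value, tau_s, n_escaped), \code{fit} (tau0, scale, r_squared) and
#'   \code{mode = "field"}.
#' @export
sweep_field <- function(trap, B_values, params = model_params(), n = 100,
                        seed = 1, t_cap = 600, dt = 1e-4,
                        criterion = "barrier") {
  tau <- nesc <- numeric(length(B_values))
  for (k in seq_along(B_values)) {
    p <- params; p$B <- B_values[k]
    er <- simulate_escape(trap, p, n = n, seed = seed + 101L * k,
                          t_cap = t_cap, dt = dt, criterion = criterion)
    tau[k] <- er$tau; nesc[k] <- er$n_escaped
  }
  fit <- if (length(B_values) >= 2) .fit_log_linear(B_values, tau)
         else list(tau0 = NA_real_, scale = NA_real_, r_squared = NA_real_)
  structure(list(summary = data.frame(x_value = B_values, tau_s = tau,
                                      n_escaped = nesc),
                 fit = fit, mode = "field"),
            class = "escape_sweep")
}

#' Escape-time sweep over symmetric-trap depths
#'
#' Builds the symmetric trap realising each requested depth (via
#' \code{\link{depth_to_dy}}), simulates the escape at a fixed field, and
#' fits \code{tau = tau0 exp(d / d_bar)}.
#'
#' @param r Pillar radius, micrometres.
#' @param d_values Requested depths, micrometres (0 < d <= r).
#' @param B Field magnitude, Tesla.
#' @param params,n,seed,t_cap,dt,criterion As in \code{\link{sweep_field}}.
#' @return An \code{"escape_sweep"} with \code{mode = "depth"}.
#' @export
sweep_depth <- function(r, d_values, B = 50e-6, params = model_params(),
                        n = 100, seed = 1, t_cap = 600, dt = 1e-4,
                        criterion = "barrier") {
  p <- params; p$B <- B
  tau <- nesc <- numeric(length(d_values))
  for (k in seq_along(d_values)) {
    trap <- make_symmetric_trap(r, depth_to_dy(r, d_values[k]))
    er <- simulate_escape(trap, p, n = n, seed = seed + 101L * k,
                          t_cap = t_cap, dt = dt, criterion = criterion)
    tau[k] <- er$tau; nesc[k] <- er$n_escaped
  }
  fit <- if (length(d_values) >= 2) .fit_log_linear(d_values, tau)
         else list(tau0 = NA_real_, scale = NA_real_, r_squared = NA_real_)
  structure(list(summary = data.frame(x_value = d_values, tau_s = tau,
                                      n_escaped = nesc),
                 fit = fit, mode = "depth"),
            class = "escape_sweep")
}

#' @export
print.escape_sweep <- function(x, ...) {
  cat(sprintf("Escape-time sweep over %s\n", x$mode))
  print(x$summary, row.names = FALSE)
  if (!is.na(x$fit$scale))
    cat(sprintf("  tau0 = %.3g s, %s = %.3g, R^2(log tau) = %.3f\n",
                x$fit$tau0, if (x$mode == "field") "B_bar [T]" else "d_bar [um]",
                x$fit$scale, x$fit$r_squared))
  invisible(x)
}

#' @export
coef.escape_sweep <- function(object, ...)
  c(tau0 = object$fit$tau0, scale = object$fit$scale)

#' @export
plot.escape_sweep <- function(x, ...) {
  s <- x$summary
  graphics::plot(s$x_value, s$tau_s, log = "y", pch = 16,
                 xlab = if (x$mode == "field") "B [T]" else "d [um]",
                 ylab = expression(tau ~ "[s]"), ...)
  if (!is.na(x$fit$scale))
    graphics::curve(x$fit$tau0 * exp(t / x$fit$scale), xname = "t", add = TRUE,
                    lty = 2)
  invisible(x)
}

#' Field step-down release from a trap
#'
#' Swimmers start at the trap apex and are first held at the initial field of
#' the schedule (equilibrating into the wedge); the field then follows the
#' piecewise-constant schedule. Reported is the occupancy: the fraction of
#' swimmers inside a triangular region opening upstream from the apex.
#'
#' @param trap A \code{\link{trap_geometry}}.
#' @param params Base parameters.
#' @param schedule data.frame \code{t}, \code{B} (first t must be 0).
#' @param n Ensemble size.
#' @param seed Integer seed.
#' @param tri_size Extent of the triangular counting region, micrometres.
#' @param duration Total simulated time; defaults to the last schedule phase
#'   lasting as long as the mean of the earlier ones.
#' @param dt,sample_interval Integration and sampling steps, seconds.
#' @return data.frame \code{t}, \code{B}, \code{occupancy}.
#' @export
field_stepdown_release <- function(trap, params = model_params(),
                                   schedule = data.frame(
                                     t = c(0, 40, 80),
                                     B = c(500e-6, 50e-6, 0)),
                                   n = 50, seed = 1, tri_size = 30,
                                   duration = NULL,
                                   dt = 1e-4, sample_interval = 0.5) {
  g <- .trap_channel(trap)
  off <- attr(g, "offset")
  apex <- trap$apex + off
  c1 <- trap$circle_1; c2 <- trap$circle_2
  n1 <- (trap$apex - c(c1$x, c1$y)) / c1$r
  n2 <- (trap$apex - c(c2$x, c2$y)) / c2$r
  bis <- n1 + n2
  if (sqrt(sum(bis^2)) < 1e-8) bis <- c(-1, 0)
  bis <- bis / sqrt(sum(bis^2))
  start <- trap$apex + 1.5 * params$sigma * bis + off
  init <- ensemble_state(matrix(rep(start, each = n), n, 2),
                         local({ set.seed(seed); stats::runif(n, -pi, pi) }))
  if (is.null(duration))
    duration <- max(schedule$t) +
      (if (nrow(schedule) > 1) mean(diff(schedule$t)) else 40)
  cfg <- simulation_config(dt = dt, duration = duration, seed = seed + 13L,
                           sample_interval = sample_interval,
                           field_schedule = schedule)
  traj <- run_simulation(init, g, params, cfg)
  # triangle: apex plus two upstream corners
  v1 <- apex
  v2 <- apex + c(-tri_size, tri_size)
  v3 <- apex + c(-tri_size, -tri_size)
  occ <- vapply(seq_along(traj$frame_t), function(f) {
    px <- traj$x[, f]; py <- traj$y[, f]
    mean(.in_triangle(px, py, v1, v2, v3))
  }, numeric(1))
  Bt <- vapply(traj$frame_t, function(t)
    schedule$B[max(which(schedule$t <= t))], numeric(1))
  data.frame(t = traj$frame_t, B = Bt, occupancy = occ)
}

.in_triangle <- function(px, py, a, b, c) {
  s1 <- (b[1] - a[1]) * (py - a[2]) - (b[2] - a[2]) * (px - a[1])
  s2 <- (c[1] - b[1]) * (py - b[2]) - (c[2] - b[2]) * (px - b[1])
  s3 <- (a[1] - c[1]) * (py - c[2]) - (a[2] - c[2]) * (px - c[1])
  (s1 >= 0 & s2 >= 0 & s3 >= 0) | (s1 <= 0 & s2 <= 0 & s3 <= 0)
}
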