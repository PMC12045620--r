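#' Obstacle-channel geometry
#'
#' A quasi-2D channel of length \code{length} (x) and width \code{width} (y)
#' filled with circular pillars that may overlap. The channel is bounded by
#' repulsive walls at y = 0 and y = width and (optionally) a wall just behind
#' the entrance so particles cannot leave upstream; the exit end is open.
#'
#' @param length,width Channel extent, micrometres.
#' @param obstacles A data.frame with columns \code{x}, \code{y}, \code{r}
#'   (centre and radius, micrometres). May be empty.
#' @param entrance_x,exit_x Entrance line and arrival threshold, micrometres.
#'   Defaults: 0 and \code{length - 5}.
#' @param walls Which confining walls exist: any subset of
#'   \code{c("left", "bottom", "top")}. The left wall surface is placed
#'   2 sigma upstream of \code{entrance_x} so that freshly seeded particles
#'   do not start in contact with it.
#' @return An object of class \code{"channel_geometry"}.
#' @examples
#' g <- channel_geometry(200, 100, data.frame(x = 100, y = 50, r = 20))
#' @export
channel_geometry <- function(length, width, obstacles = empty_obstacles(),
                             entrance_x = 0, exit_x = length - 5,
                             walls = c("left", "bottom", "top")) {
  stopifnot(length > 0, width > 0)
  obstacles <- as.data.frame(obstacles)
  if (nrow(obstacles) > 0) {
    stopifnot(all(c("x", "y", "r") %in% names(obstacles)),
              all(obstacles$r > 0))
    obstacles <- obstacles[, c("x", "y", "r")]
  } else {
    obstacles <- empty_obstacles()
  }
  if (!(entrance_x >= 0 && entrance_x < exit_x && exit_x <= length))
    stop("need 0 <= entrance_x < exit_x <= length")
  structure(list(length = length, width = width, obstacles = obstacles,
                 entrance_x = entrance_x, exit_x = exit_x,
                 walls = intersect(walls, c("left", "bottom", "top"))),
            class = "channel_geometry")
}

#' @rdname channel_geometry
#' @export
empty_obstacles <- function()
  data.frame(x = numeric(0), y = numeric(0), r = numeric(0))

#' @export
print.channel_geometry <- function(x, ...) {
  cat(sprintf("Obstacle channel %g x %g um, %d obstacles\n",
              x$length, x$width, nrow(x$obstacles)))
  cat(sprintf("  entrance x = %g, exit threshold x = %g, walls: %s\n",
              x$entrance_x, x$exit_x,
              if (length(x$walls)) paste(x$walls, collapse = ", ") else "none"))
  invisible(x)
}

#' @export
plot.channel_geometry <- function(x, ...) {
  graphics::plot(NA, xlim = c(0, x$length), ylim = c(0, x$width), asp = 1,
                 xlab = "x [um]", ylab = "y [um]", ...)
  ob <- x$obstacles
  if (nrow(ob)) graphics::symbols(ob$x, ob$y, circles = ob$r, inches = FALSE,
                                  add = TRUE, bg = "grey70", fg = "grey40")
  graphics::abline(v = x$exit_x, lty = 2, col = "red")
  invisible(x)
}

# wall description used by both the R reference path and the C++ engine:
# each wall is a half-plane with fluid on the side where nx*x + ny*y - c > 0;
# that expression is the distance h from the particle centre to the wall.
.wall_matrix <- function(geometry, sigma) {
  w <- geometry$walls
  m <- matrix(numeric(0), ncol = 3)
  if ("left" %in% w)
    m <- rbind(m, c(1, 0, geometry$entrance_x - 2 * sigma))
  if ("bottom" %in% w) m <- rbind(m, c(0, 1, 0))
  if ("top" %in% w) m <- rbind(m, c(0, -1, -geometry$width))
  colnames(m) <- c("nx", "ny", "c")
  m
}

#' Nearest solid surface seen from a point
#'
#' Finds the obstacle or wall whose surface is nearest to \code{position} and
#' returns the virtual-particle contact used by the repulsive surface force:
#' a virtual particle of the same diameter sits just inside the solid with its
#' surface at the nearest surface point, so the centre-to-centre vector
#' \code{rS} has length h + sigma/2, pointing from the solid into the fluid.
#'
#' @param position 2-vector, micrometres.
#' @param geometry A \code{\link{channel_geometry}}.
#' @param sigma Particle diameter, micrometres.
#' @param range Return \code{NULL} when the nearest surface is farther than
#'   this distance (centre-to-surface). Default \code{Inf} returns the nearest
#'   contact regardless; the engine itself only evaluates forces within the
#'   WCA cutoff.
#' @return \code{NULL}, or a list with \code{obstacle_id} (row index of the
#'   obstacle, or \code{"wall:k"}), \code{h} (centre-to-surface distance, um)
#'   and \code{rS} (2-vector, um). Ties are broken towards the lowest obstacle
#'   index; walls lose against obstacles.
#' @examples
#' g <- channel_geometry(200, 200, data.frame(x = 0, y = 100, r = 50),
#'                       walls = character(0))
#' nearest_surface_contact(c(60, 100), g, sigma = 1)
#' @export
nearest_surface_contact <- function(position, geometry, sigma, range = Inf) {
  stopifnot(length(position) == 2)
  ob <- geometry$obstacles
  best_h <- Inf; best_n <- NULL; best_id <- NULL
  if (nrow(ob)) {
    d <- sqrt((position[1] - ob$x)^2 + (position[2] - ob$y)^2)
    h <- d - ob$r
    i <- which.min(h)              # which.min takes the first (lowest index) tie
    if (h[i] < -sigma / 4)
      stop("degenerate position: particle centre inside a solid obstacle")
    if (d[i] > 0) {
      best_h <- h[i]
      best_n <- c(position[1] - ob$x[i], position[2] - ob$y[i]) / d[i]
      best_id <- i
    }
  }
  wm <- .wall_matrix(geometry, sigma)
  if (nrow(wm)) for (k in seq_len(nrow(wm))) {
    h <- wm[k, 1] * position[1] + wm[k, 2] * position[2] - wm[k, 3]
    if (h < -sigma / 4) stop("degenerate position: particle centre beyond a wall")
    if (h < best_h) {              # strict: walls come after obstacles on ties
      best_h <- unname(h)
      best_n <- unname(wm[k, 1:2])
      best_id <- paste0("wall:", k)
    }
  }
  if (!is.finite(best_h) || best_h >= range) return(NULL)
  list(obstacle_id = best_id, h = best_h,
       rS = (best_h + sigma / 2) * best_n)
}

#' Is a point inside the solid phase?
#' @inheritParams nearest_surface_contact
#' @return Logical.
#' @export
point_in_solid <- function(position, geometry, sigma = 1) {
  ob <- geometry$obstacles
  if (nrow(ob) &&
      any((position[1] - ob$x)^2 + (position[2] - ob$y)^2 < ob$r^2))
    return(TRUE)
  wm <- .wall_matrix(geometry, sigma)
  if (nrow(wm) &&
      any(wm[, 1] * position[1] + wm[, 2] * position[2] - wm[, 3] < 0))
    return(TRUE)
  FALSE
}

#' Read / write channel geometry as JSON
#'
#' Schema: \code{\{length_um, width_um, entrance_x_um, exit_x_um, walls,
#' obstacles: [\{x_um, y_um, r_um\}]\}}.
#'
#' @param geometry A \code{\link{channel_geometry}}.
#' @param path File path.
#' @return \code{read_geometry_json} returns a \code{channel_geometry};
#'   \code{write_geometry_json} returns \code{path} invisibly.
#' @export
write_geometry_json <- function(geometry, path) {
  ob <- geometry$obstacles
  x <- list(length_um = geometry$length, width_um = geometry$width,
            entrance_x_um = geometry$entrance_x, exit_x_um = geometry$exit_x,
            walls = as.list(geometry$walls),
            obstacles = if (nrow(ob))
              lapply(seq_len(nrow(ob)), function(i)
                list(x_um = ob$x[i], y_um = ob$y[i], r_um = ob$r[i]))
            else list())
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_geometry_json
#' @export
read_geometry_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ob <- x$obstacles
  obstacles <- if (is.data.frame(ob) && nrow(ob))
    data.frame(x = ob$x_um, y = ob$y_um, r = ob$r_um) else empty_obstacles()
  channel_geometry(x$length_um, x$width_um, obstacles,
                   entrance_x = x$entrance_x_um, exit_x = x$exit_x_um,
                   walls = unlist(x$walls))
}
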