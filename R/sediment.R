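#' Generate a synthetic sediment-mimicking obstacle channel
#'
#' Circular pillars are added by random sequential addition (overlaps
#' permitted, as in natural packings) with diameters drawn log-normally --
#' Gaussian in log diameter with location \code{log_diam_mu} and width
#' parameter \code{log_diam_c} of the form \code{a exp(-(x - mu)^2 / c^2)},
#' i.e. standard deviation \code{c / sqrt(2)} -- until the rasterised solid
#' fraction reaches \code{target_solid_fraction}. The defaults reproduce the
#' measured statistics of a silt-like freshwater sediment: 61 % solid, mean
#' grain diameter exp(3.83) = 46 um.
#'
#' @param length,width Channel extent, micrometres.
#' @param target_solid_fraction Desired solid area fraction, in [0, 0.85).
#' @param log_diam_mu,log_diam_c Gaussian parameters of the log-diameter
#'   distribution (log micrometres).
#' @param seed Integer seed; generation is deterministic given the seed.
#' @param pixel_size Rasterisation step used to track the solid fraction
#'   during placement, micrometres.
#' @param max_obstacles Safety bound on placement attempts.
#' @return A \code{\link{channel_geometry}} whose rasterised solid fraction is
#'   within 0.02 of the target.
#' @examples
#' g <- generate_obstacle_channel(400, 300, 0.3, seed = 1)
#' @export
generate_obstacle_channel <- function(length, width,
                                      target_solid_fraction = 0.61,
                                      log_diam_mu = 3.83,
                                      log_diam_c = 0.5903,
                                      seed = 1, pixel_size = 2,
                                      max_obstacles = 50000) {
  stopifnot(target_solid_fraction >= 0, target_solid_fraction < 0.85)
  if (target_solid_fraction == 0)
    return(channel_geometry(length, width))
  nx <- max(1L, round(length / pixel_size))
  ny <- max(1L, round(width / pixel_size))
  solid <- matrix(FALSE, nx, ny)
  npx <- nx * ny
  cx_grid <- (seq_len(nx) - 0.5) * pixel_size
  cy_grid <- (seq_len(ny) - 0.5) * pixel_size
  set.seed(seed)
  xs <- ys <- rs <- numeric(0)
  frac <- 0
  for (k in seq_len(max_obstacles)) {
    if (frac >= target_solid_fraction) break
    r <- exp(stats::rnorm(1, log_diam_mu, log_diam_c / sqrt(2))) / 2
    cx <- stats::runif(1, 0, length)
    cy <- stats::runif(1, 0, width)
    i0 <- max(1L, ceiling((cx - r) / pixel_size + 0.5))
    i1 <- min(nx, floor((cx + r) / pixel_size + 0.5))
    j0 <- max(1L, ceiling((cy - r) / pixel_size + 0.5))
    j1 <- min(ny, floor((cy + r) / pixel_size + 0.5))
    if (i1 >= i0 && j1 >= j0) {
      ii <- i0:i1; jj <- j0:j1
      dx2 <- (cx_grid[ii] - cx)^2
      dy2 <- (cy_grid[jj] - cy)^2
      inside <- outer(dx2, dy2, "+") <= r^2
      block <- solid[ii, jj, drop = FALSE]
      added <- sum(inside & !block)
      if (frac + added / npx > target_solid_fraction + 0.015) next  # resample
      if (added > 0) {
        solid[ii, jj] <- block | inside
        frac <- frac + added / npx
      }
    }
    xs <- c(xs, cx); ys <- c(ys, cy); rs <- c(rs, r)
  }
  if (frac < target_solid_fraction - 0.02)
    stop("could not reach the target solid fraction within max_obstacles")
  channel_geometry(length, width,
                   data.frame(x = xs, y = ys, r = rs))
}

#' Binary grain mask
#'
#' @param raster Logical matrix, TRUE = solid. Rows index x, columns index y.
#' @param pixel_size Micrometres per pixel.
#' @return List of class \code{"grain_mask"}.
#' @export
grain_mask <- function(raster, pixel_size) {
  stopifnot(is.matrix(raster), pixel_size > 0)
  structure(list(raster = raster, pixel_size = pixel_size),
            class = "grain_mask")
}

#' @export
print.grain_mask <- function(x, ...) {
  cat(sprintf("Grain mask %d x %d px at %g um/px, solid fraction %.3f\n",
              nrow(x$raster), ncol(x$raster), x$pixel_size,
              solid_fraction(x)))
  invisible(x)
}

#' Rasterise an obstacle geometry into a binary mask
#'
#' A pixel is solid iff its centre lies inside at least one circle.
#'
#' @param geometry A \code{\link{channel_geometry}}.
#' @param pixel_size Micrometres per pixel (default 1.56, the tomography
#'   resolution the defaults were derived from).
#' @return A \code{\link{grain_mask}}.
#' @export
rasterize <- function(geometry, pixel_size = 1.56) {
  nx <- max(1L, round(geometry$length / pixel_size))
  ny <- max(1L, round(geometry$width / pixel_size))
  solid <- matrix(FALSE, nx, ny)
  ob <- geometry$obstacles
  if (nrow(ob)) {
    cx_grid <- (seq_len(nx) - 0.5) * pixel_size
    cy_grid <- (seq_len(ny) - 0.5) * pixel_size
    for (k in seq_len(nrow(ob))) {
      r <- ob$r[k]; cx <- ob$x[k]; cy <- ob$y[k]
      i0 <- max(1L, ceiling((cx - r) / pixel_size + 0.5))
      i1 <- min(nx, floor((cx + r) / pixel_size + 0.5))
      j0 <- max(1L, ceiling((cy - r) / pixel_size + 0.5))
      j1 <- min(ny, floor((cy + r) / pixel_size + 0.5))
      if (i1 < i0 || j1 < j0) next
      ii <- i0:i1; jj <- j0:j1
      inside <- outer((cx_grid[ii] - cx)^2, (cy_grid[jj] - cy)^2, "+") <= r^2
      solid[ii, jj] <- solid[ii, jj] | inside
    }
  }
  grain_mask(solid, pixel_size)
}

#' Solid (sand) area fraction of a mask
#' @param mask A \code{\link{grain_mask}}.
#' @return Fraction of solid pixels.
#' @export
solid_fraction <- function(mask) mean(mask$raster)

#' Does a channel admit a connected fluid path from entrance to exit?
#'
#' Rasterises the geometry, optionally erodes the fluid phase by a clearance
#' radius (the swimmer is a disc, not a point), and checks 4-connectivity of
#' the fluid between the entrance and exit columns. Random packings at the
#' default 61 % solid fraction are close to the 2D continuum percolation
#' threshold, so individual realisations may or may not be traversable;
#' transit experiments precondition on this purely geometric test.
#'
#' @param geometry A \code{\link{channel_geometry}}.
#' @param pixel_size Raster resolution, micrometres.
#' @param clearance Radius to erode off the fluid phase, micrometres
#'   (default half a swimmer diameter).
#' @return TRUE if a percolating fluid path exists.
#' @export
channel_percolates <- function(geometry, pixel_size = 2, clearance = 0.5) {
  m <- rasterize(geometry, pixel_size)
  fluid <- !m$raster
  er_px <- floor(clearance / pixel_size)
  img <- EBImage::Image(fluid * 1)
  if (er_px >= 1)
    img <- EBImage::erode(img, EBImage::makeBrush(2 * er_px + 1, "diamond"))
  L <- EBImage::imageData(EBImage::bwlabel(img))
  i_in <- max(1L, min(nrow(L), ceiling(geometry$entrance_x / pixel_size)))
  i_out <- max(1L, min(nrow(L), ceiling(geometry$exit_x / pixel_size)))
  common <- setdiff(intersect(unique(L[i_in, ]), unique(L[i_out, ])), 0)
  length(common) > 0
}
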