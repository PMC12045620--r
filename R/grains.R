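#' Fit circles to the grains of a binary mask
#'
#' Reimplementation of the tomography-slice granulometry: touching grains are
#' separated by eroding the mask with a diamond structuring element, each
#' eroded connected component becomes a marker, the full (uneroded) solid
#' phase is partitioned among the markers by nearest-marker propagation, and
#' each grain is summarised by the centroid of its marker and the
#' equivalent-area radius of its assigned full component. Measuring radii on
#' the uneroded partition avoids the systematic shrinkage an eroded-radius
#' estimate would carry.
#'
#' @param mask A \code{\link{grain_mask}}.
#' @param erosion_radius_px Radius (pixels) of the diamond structuring
#'   element; default 9.
#' @return data.frame with columns \code{x}, \code{y}, \code{r} (micrometres);
#'   zero rows for an all-fluid mask.
#' @export
fit_grain_circles <- function(mask, erosion_radius_px = 9) {
  stopifnot(inherits(mask, "grain_mask"))
  img <- EBImage::Image(mask$raster * 1)
  kern <- EBImage::makeBrush(2 * erosion_radius_px + 1, shape = "diamond")
  eroded <- EBImage::erode(img, kern)
  markers <- EBImage::bwlabel(eroded)
  nmark <- max(markers)
  if (nmark == 0) return(empty_obstacles())
  # assign every solid pixel to its nearest marker (Voronoi propagation)
  lab <- EBImage::propagate(img, seeds = markers, mask = img)
  labm <- EBImage::imageData(lab)
  mm <- EBImage::imageData(markers)
  px <- mask$pixel_size
  ids <- seq_len(nmark)
  # centroids from the markers, areas from the assigned full components
  idx <- which(mm > 0)
  mi <- ((idx - 1) %% nrow(mm)) + 1
  mj <- ((idx - 1) %/% nrow(mm)) + 1
  cx <- tapply((mi - 0.5) * px, mm[idx], mean)
  cy <- tapply((mj - 0.5) * px, mm[idx], mean)
  area <- tabulate(labm[labm > 0], nbins = nmark) * px^2
  keep <- area > 0
  data.frame(x = as.numeric(cx[as.character(ids)])[keep],
             y = as.numeric(cy[as.character(ids)])[keep],
             r = sqrt(area[keep] / pi))
}

# least-squares fit of a * exp(-(x - mu)^2 / c^2) to a histogram of `values`
.fit_gauss_hist <- function(values, nbins = 25) {
  h <- graphics::hist(values, breaks = nbins, plot = FALSE)
  df <- data.frame(x = h$mids, y = h$density)
  start <- list(a = max(df$y), mu = mean(values),
                c = sqrt(2) * stats::sd(values))
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(-(x - mu)^2 / c^2), data = df,
                      start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("Gaussian histogram fit failed: ",
                             conditionMessage(e)))
  cf <- stats::coef(fit)
  cf["c"] <- abs(cf["c"])
  list(a = unname(cf["a"]), mu = unname(cf["mu"]), c = unname(cf["c"]),
       fit = fit, hist = df)
}

#' Grain-size statistics of a fitted-circle population
#'
#' Histograms the natural log of the grain diameters and fits the Gaussian
#' \code{a exp(-(x - mu)^2 / c^2)} by least squares; the mean grain diameter
#' is \code{exp(mu)}. The solid fraction is taken from the mask.
#'
#' @param circles data.frame with a radius column \code{r} (micrometres),
#'   e.g. from \code{\link{fit_grain_circles}}.
#' @param mask Optional \code{\link{grain_mask}} for the solid fraction.
#' @param nbins Histogram bin count for the fit.
#' @return Object of class \code{"grain_statistics"}: \code{circles},
#'   \code{solid_fraction}, \code{log_fit} (a, mu, c), \code{mean_diameter}.
#' @examples
#' set.seed(1)
#' circ <- data.frame(r = exp(rnorm(500, 3.83, 0.5903 / sqrt(2))) / 2)
#' gs <- grain_statistics(circ)
#' gs$mean_diameter  # ~46 um
#' @export
grain_statistics <- function(circles, mask = NULL, nbins = 25) {
  if (nrow(circles) < 10)
    stop("need at least 10 circles for a stable Gaussian fit")
  fit <- .fit_gauss_hist(log(2 * circles$r), nbins = nbins)
  structure(list(circles = circles,
                 solid_fraction = if (!is.null(mask)) solid_fraction(mask)
                                  else NA_real_,
                 log_fit = fit[c("a", "mu", "c")],
                 mean_diameter = exp(fit$mu),
                 hist = fit$hist),
            class = "grain_statistics")
}

#' @export
print.grain_statistics <- function(x, ...) {
  cat(sprintf("Grain statistics from %d circles\n", nrow(x$circles)))
  cat(sprintf("  log-diameter fit: mu = %.3f, c = %.3f  (a exp(-(x-mu)^2/c^2))\n",
              x$log_fit$mu, x$log_fit$c))
  cat(sprintf("  mean grain diameter exp(mu) = %.1f um\n", x$mean_diameter))
  if (!is.na(x$solid_fraction))
    cat(sprintf("  solid fraction = %.3f\n", x$solid_fraction))
  invisible(x)
}

#' @export
plot.grain_statistics <- function(x, ...) {
  with(x$hist, graphics::plot(x, y, type = "h", lwd = 4, col = "grey60",
                              xlab = "ln(diameter [um])", ylab = "density", ...))
  xx <- seq(min(x$hist$x), max(x$hist$x), length.out = 200)
  graphics::lines(xx, x$log_fit$a * exp(-(xx - x$log_fit$mu)^2 / x$log_fit$c^2),
                  col = "red3", lwd = 2)
  invisible(x)
}

#' Water-gap statistics of a mask (2D local thickness of the fluid phase)
#'
#' For every fluid pixel, the gap size is the diameter of the largest disc
#' that lies entirely in the fluid and contains the pixel; disc radii are
#' capped at half the smaller mask dimension and the image border itself does
#' not limit a disc. This is a two-dimensional analogue of the trabecular
#' separation used in 3D morphometry of the solid/void structure.
#'
#' @param mask A \code{\link{grain_mask}} with a non-empty fluid phase.
#' @param fit Fit a Gaussian \code{a exp(-(x - mu)^2 / c^2)} to the gap-size
#'   histogram (needs a spread of gap values).
#' @param nbins Histogram bins for the fit.
#' @return Object of class \code{"gap_statistics"}: \code{gap_map} (matrix of
#'   gap sizes, micrometres, NA on solid), \code{gap_sizes} (fluid-pixel
#'   values), and \code{gauss_fit} (a, mu, c) or NULL.
#' @export
gap_statistics <- function(mask, fit = TRUE, nbins = 25) {
  stopifnot(inherits(mask, "grain_mask"))
  solid <- mask$raster
  if (all(solid)) stop("mask has no fluid phase")
  cap_px <- min(dim(solid)) / 2
  if (!any(solid)) {
    D <- matrix(cap_px, nrow(solid), ncol(solid))
  } else {
    # distance (px) from each fluid pixel to the nearest solid pixel
    D <- EBImage::imageData(EBImage::distmap(EBImage::Image(1 - solid * 1)))
    D[D > cap_px] <- cap_px
  }
  lt <- .local_thickness_cpp(D) * mask$pixel_size
  lt[solid] <- NA_real_
  gaps <- lt[!solid]
  gf <- NULL
  if (fit && length(unique(round(gaps, 6))) > 5)
    gf <- tryCatch(.fit_gauss_hist(gaps, nbins = nbins)[c("a", "mu", "c")],
                   error = function(e) NULL)
  structure(list(gap_map = lt, gap_sizes = gaps, gauss_fit = gf,
                 pixel_size = mask$pixel_size),
            class = "gap_statistics")
}

#' @export
print.gap_statistics <- function(x, ...) {
  cat(sprintf("Water-gap statistics over %d fluid pixels\n", length(x$gap_sizes)))
  cat(sprintf("  median gap %.1f um, modal gap %.1f um\n",
              stats::median(x$gap_sizes),
              as.numeric(names(which.max(table(round(x$gap_sizes)))))))
  if (!is.null(x$gauss_fit))
    cat(sprintf("  Gaussian fit: mu = %.1f um, c = %.1f um\n",
                x$gauss_fit$mu, x$gauss_fit$c))
  invisible(x)
}
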