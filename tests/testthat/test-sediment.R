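test_that("channel generation hits the target solid fraction deterministically", {
  # zero target -> no obstacles
  g0 <- generate_obstacle_channel(500, 400, 0, seed = 1)
  expect_equal(nrow(g0$obstacles), 0L)

  g <- generate_obstacle_channel(800, 600, 0.61, seed = 7)
  m <- rasterize(g, 2)
  expect_gte(solid_fraction(m), 0.59)
  expect_lte(solid_fraction(m), 0.63)
  # determinism
  g2 <- generate_obstacle_channel(800, 600, 0.61, seed = 7)
  expect_identical(g$obstacles, g2$obstacles)

  # geometric mean of grain diameters ~ exp(3.83) = 46 um (law of large numbers)
  gl <- generate_obstacle_channel(3000, 2500, 0.61, seed = 3)
  expect_gt(nrow(gl$obstacles), 500)
  gm <- exp(mean(log(2 * gl$obstacles$r)))
  expect_equal(gm, exp(3.83), tolerance = 0.05)
})

test_that("rasterisation reproduces analytic circle and union areas", {
  # empty geometry -> all fluid
  m0 <- rasterize(channel_geometry(100, 80), 2)
  expect_equal(solid_fraction(m0), 0)

  # single disc: pixel count ~ pi r^2 at the tomography resolution
  g1 <- channel_geometry(300, 300, data.frame(x = 150, y = 150, r = 50),
                         walls = character(0))
  m1 <- rasterize(g1, 1.56)
  expect_equal(sum(m1$raster) * 1.56^2, pi * 50^2, tolerance = 0.02)

  # union of two overlapping circles vs a Monte-Carlo oracle
  g2 <- channel_geometry(300, 300,
                         data.frame(x = c(120, 170), y = c(150, 150),
                                    r = c(50, 40)), walls = character(0))
  m2 <- rasterize(g2, 1)
  set.seed(42)
  qx <- runif(4e5, 0, 300); qy <- runif(4e5, 0, 300)
  inside <- ((qx - 120)^2 + (qy - 150)^2 <= 50^2) |
    ((qx - 170)^2 + (qy - 150)^2 <= 40^2)
  expect_equal(sum(m2$raster) * 1, 300^2 * mean(inside),
               tolerance = 0.01)
})

test_that("rasterised solid fraction converges to the analytic union area", {
  g <- channel_geometry(200, 200,
                        data.frame(x = c(80, 120), y = c(100, 100), r = c(40, 35)),
                        walls = character(0))
  # exact union area of two discs (closed-form lens overlap)
  d <- 40; r1 <- 40; r2 <- 35
  lens <- r1^2 * acos((d^2 + r1^2 - r2^2) / (2 * d * r1)) +
    r2^2 * acos((d^2 + r2^2 - r1^2) / (2 * d * r2)) -
    0.5 * sqrt((-d + r1 + r2) * (d + r1 - r2) * (d - r1 + r2) * (d + r1 + r2))
  union_area <- pi * r1^2 + pi * r2^2 - lens
  err <- sapply(c(2, 0.5), function(px) {
    abs(sum(rasterize(g, px)$raster) * px^2 - union_area) / union_area
  })
  expect_lt(err[2], err[1])      # finer raster is closer
  expect_lt(err[2], 0.005)
})

test_that("percolation check distinguishes open and blocked channels", {
  open <- channel_geometry(200, 100)
  expect_true(channel_percolates(open))
  blocked <- channel_geometry(200, 100,
                              data.frame(x = 100, y = 50, r = 60))
  expect_false(channel_percolates(blocked))
})

test_that("geometry JSON round-trips", {
  g <- generate_obstacle_channel(300, 200, 0.3, seed = 5)
  path <- tempfile(fileext = ".json")
  write_geometry_json(g, path)
  g2 <- read_geometry_json(path)
  expect_equal(g2$obstacles, g$obstacles, tolerance = 1e-12)
  expect_equal(g2$length, g$length)
  expect_equal(g2$walls, g$walls)
  unlink(path)
})
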