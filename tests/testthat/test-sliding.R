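# build a synthetic trajectory object without running the engine
fake_traj <- function(t, x, y, geometry, params = model_params()) {
  structure(list(frame_t = t, x = matrix(x, 1), y = matrix(y, 1),
                 phi = matrix(0, 1, length(t)),
                 geometry = geometry, params = params),
            class = "abp_trajectory")
}

test_that("sliding events require proximity and interaction-band contact", {
  g <- channel_geometry(300, 300, data.frame(x = 150, y = 150, r = 50),
                        walls = character(0))
  # a track that never comes within 2 um of the surface: no events
  t <- seq(0, 10, by = 0.05)
  far <- fake_traj(t, x = 10 + 5 * t, y = rep(50, length(t)), g)
  expect_equal(nrow(detect_sliding_events(far)), 0L)

  # an arc hugging the circle at constant h = 0.3 (inside the interaction
  # band): sliding distance ~ (R + h) * theta
  theta <- seq(0, 1.2, length.out = 400)
  R <- 50; h <- 0.3
  arc <- fake_traj(seq_along(theta) * 0.01,
                   x = 150 + (R + h) * cos(theta),
                   y = 150 + (R + h) * sin(theta), g)
  ev <- detect_sliding_events(arc)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$slide_um, (R + h) * 1.2, tolerance = 0.02)
  expect_equal(ev$obstacle_id, 1)

  # same arc at h = 1.5: within the sliding band but never reaching the
  # interaction band -> excluded
  arc2 <- fake_traj(seq_along(theta) * 0.01,
                    x = 150 + (R + 1.5) * cos(theta),
                    y = 150 + (R + 1.5) * sin(theta), g)
  expect_equal(nrow(detect_sliding_events(arc2)), 0L)
})

test_that("arc-length discretisation converges under refinement", {
  g <- channel_geometry(300, 300, data.frame(x = 150, y = 150, r = 50),
                        walls = character(0))
  R <- 50; h <- 0.3
  slide_at <- function(npts) {
    theta <- seq(0, 1.2, length.out = npts)
    tr <- fake_traj(seq_along(theta) * 0.01,
                    x = 150 + (R + h) * cos(theta),
                    y = 150 + (R + h) * sin(theta), g)
    detect_sliding_events(tr)$slide_um
  }
  s1 <- slide_at(200); s2 <- slide_at(400)
  expect_lt(abs(s2 - s1) / s1, 0.01)
})

test_that("sliding histograms normalise and bin correctly", {
  ev <- data.frame(slide_um = c(1, 1, 3))
  h <- sliding_histogram(ev, bin_edges = 0:4)
  expect_equal(h$freq, c(2 / 3, 0, 1 / 3, 0))
  expect_equal(sum(h$freq), 1)
  # single event: all mass in its bin
  h1 <- sliding_histogram(data.frame(slide_um = 5), bin_edges = seq(0, 30, 2))
  expect_equal(sum(h1$freq), 1)
  expect_equal(h1$freq[h1$mid == 5], 1)
  expect_error(sliding_histogram(data.frame(slide_um = numeric(0))), "no sliding")
})

test_that("sliding distances respond to alpha and depend weakly on curvature", {
  # distributions at alpha = 0.05 and 0.8 differ far more than two same-alpha
  # replicas (Kolmogorov-Smirnov distances)
  ks <- function(a, b) suppressWarnings(stats::ks.test(a, b)$statistic)
  e_lo <- simulate_sliding_events(0.05, n_particles = 40, duration = 30, seed = 21)
  e_hi <- simulate_sliding_events(0.8, n_particles = 40, duration = 30, seed = 22)
  e_lo2 <- simulate_sliding_events(0.05, n_particles = 40, duration = 30, seed = 23)
  expect_gt(ks(e_lo$slide_um, e_hi$slide_um), ks(e_lo$slide_um, e_lo2$slide_um))

  # mean sliding distance on R = 30 vs R = 80 pillars differs by < 1.5x
  gs <- function(R) channel_geometry(2 * R + 120, 2 * R + 120,
                                     data.frame(x = R + 60, y = R + 60, r = R),
                                     walls = c("left", "bottom", "top"))
  e30 <- simulate_sliding_events(0.2, n_particles = 50, duration = 30,
                                 seed = 31, geometry = gs(30))
  e80 <- simulate_sliding_events(0.2, n_particles = 50, duration = 30,
                                 seed = 31, geometry = gs(80))
  ratio <- mean(e80$slide_um) / mean(e30$slide_um)
  expect_gt(ratio, 1 / 1.5)
  expect_lt(ratio, 1.5)
})

test_that("single-element calibration grid returns that element", {
  ref <- data.frame(mid = seq(1, 29, by = 2), freq = c(1, rep(0, 14)))
  cal <- calibrate_alpha(ref, alpha_grid = 0.2, n_particles = 10,
                         duration = 10, seed = 2)
  expect_equal(cal$alpha_star, 0.2)
  expect_equal(coef(cal), c(alpha = 0.2))
})
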