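test_that("symmetric trap geometry: apex, tangency, and failure modes", {
  tr <- make_symmetric_trap(50, 100)           # tangent pillars
  expect_equal(tr$apex, c(0, 0), tolerance = 1e-9)
  expect_equal(trap_depth(tr), 50)             # r - sqrt(r^2 - (dy/2)^2) = r
  expect_error(make_symmetric_trap(50, 101), "no trap")

  tr2 <- make_symmetric_trap(50, 80)
  expect_equal(tr2$apex, c(-30, 0), tolerance = 1e-9)
  expect_equal(trap_depth(tr2), 20, tolerance = 1e-12)

  # nearly coincident circles leave no wedge
  shallow <- make_symmetric_trap(50, 1)
  expect_lt(trap_depth(shallow), 0.01)

  # depth inversion: d = 20 at r = 50 -> dy = 80
  expect_equal(depth_to_dy(50, 20), 80, tolerance = 1e-12)
  expect_error(depth_to_dy(50, 60), "depth")
})

# brute-force oracle: densely sample both circle boundaries. The apex is the
# upstream-most point lying on both boundaries; a boundary path from the apex
# to a circle's upstream pole reaches, at its end, that circle's minimal x,
# so the upstream excursion needed along circle i is x_apex - min_x(circle i)
# and the trap depth is the smaller of the two (minimax over escape routes).
depth_oracle <- function(tr) {
  c1 <- tr$circle_1; c2 <- tr$circle_2
  th <- seq(0, 2 * pi, length.out = 40001)
  f <- function(a) sqrt((c1$x + c1$r * cos(a) - c2$x)^2 +
                          (c1$y + c1$r * sin(a) - c2$y)^2) - c2$r
  fv <- f(th)
  flip <- which(fv[-1] * fv[-length(fv)] <= 0)
  if (!length(flip)) return(NA_real_)
  roots <- vapply(flip, function(i)
    uniroot(f, c(th[i], th[i + 1]), tol = 1e-12)$root, numeric(1))
  apex_x <- min(c1$x + c1$r * cos(roots))
  min(apex_x - (c1$x - c1$r), apex_x - (c2$x - c2$r))
}

test_that("trap depth agrees with a boundary-path oracle on random traps", {
  depths <- oracle <- numeric(50)
  for (s in 1:50) {
    tr <- sample_random_trap(seed = s)
    depths[s] <- trap_depth(tr)
    oracle[s] <- depth_oracle(tr)
  }
  expect_lt(max(abs(depths - oracle)), 0.1)
})

test_that("random traps are deterministic, valid, and span depths", {
  t1 <- sample_random_trap(seed = 7)
  t2 <- sample_random_trap(seed = 7)
  expect_identical(t1, t2)
  ds <- sapply(1:100, function(s) trap_depth(sample_random_trap(seed = s)))
  expect_true(all(ds > 0.5))
  expect_gt(max(ds) / min(ds), 10)   # more than a decade of depths
})

test_that("censored exponential MLE handles plain and censored samples", {
  expect_equal(fit_exponential_mean(c(1, 2, 3)), 2)
  expect_equal(fit_exponential_mean(c(2, 10), c(FALSE, TRUE)), 12)
  expect_error(fit_exponential_mean(c(5, 6), c(TRUE, TRUE)), "uncensored")
  # estimator consistency on a large exponential sample
  set.seed(8)
  x <- rexp(10000, rate = 1 / 5)
  expect_lt(abs(fit_exponential_mean(x) - 5), 0.15)
  # censoring at the cap keeps the estimator unbiased
  cen <- x > 8
  xc <- pmin(x, 8)
  expect_lt(abs(fit_exponential_mean(xc, cen) - 5), 0.2)
})

test_that("escape simulation: empty result, field dependence, determinism", {
  trap <- make_symmetric_trap(50, 100)
  expect_equal(length(simulate_escape(trap, n = 0)$escape_times), 0L)

  p0 <- model_params(B = 0)
  p50 <- model_params(B = 50e-6)
  # barrier passage: field-free escape is easier, tau strictly smaller
  e0 <- simulate_escape(trap, p0, n = 30, seed = 4, t_cap = 300,
                        criterion = "barrier")
  e50 <- simulate_escape(trap, p50, n = 30, seed = 4, t_cap = 300,
                         criterion = "barrier")
  expect_lt(e0$tau, e50$tau)
  expect_gt(e0$n_escaped, 0)
  # deterministic per seed
  e50c <- simulate_escape(trap, p50, n = 30, seed = 4, t_cap = 300)
  e50b <- simulate_escape(trap, p50, n = 30, seed = 4, t_cap = 300)
  expect_identical(e50c$escape_times, e50b$escape_times)
})

test_that("field step-down releases trapped swimmers in stages", {
  trap <- make_symmetric_trap(50, 100)
  # n = 1: occupancy is 0 or 1 at every sample
  occ1 <- field_stepdown_release(trap, n = 1, seed = 2,
                                 schedule = data.frame(t = c(0, 5),
                                                       B = c(500e-6, 0)),
                                 duration = 10, sample_interval = 0.5)
  expect_true(all(occ1$occupancy %in% c(0, 1)))

  sched <- data.frame(t = c(0, 30, 60), B = c(500e-6, 50e-6, 0))
  occ <- field_stepdown_release(trap, n = 25, seed = 3, schedule = sched,
                                duration = 90, sample_interval = 0.5)
  phase_tail <- function(a, b)  # mean occupancy in the last 10 s of a phase
    mean(occ$occupancy[occ$t > b - 10 & occ$t <= b])
  tails <- c(phase_tail(0, 30), phase_tail(30, 60), phase_tail(60, 90))
  expect_true(all(diff(tails) < 0))
  # strong-field control: occupancy stays high throughout
  ctrl <- field_stepdown_release(trap, n = 25, seed = 3,
                                 schedule = data.frame(t = 0, B = 500e-6),
                                 duration = 90, sample_interval = 0.5)
  expect_gt(mean(ctrl$occupancy[ctrl$t > 80]), 0.8)
})
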