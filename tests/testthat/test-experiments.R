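# scaled-down study conditions keep these unit tests fast; the full-size runs
# live in the acceptance suite

small_cfg <- solver_config(dt = 0.01, iterations = 5)

test_that("zero loading velocity produces a zero force curve", {
  nl <- run_nonlinearity(velocities = 0, max_displacement = 5,
                         config = small_cfg, edge = 20, divisions = 2)
  expect_lt(max(nl$series$force), 1e-6)
  expect_lt(max(nl$series$displacement), 1e-9)
})

test_that("faster loading produces pointwise larger reaction forces", {
  nl <- run_nonlinearity(velocities = c(2, 4), max_displacement = 4,
                         config = small_cfg, edge = 20, divisions = 2)
  s <- nl$series
  d <- seq(0.5, 3.5, by = 0.5)
  slow <- approx(s$displacement[s$velocity == 2],
                 moving_average(s$t[s$velocity == 2], s$force[s$velocity == 2]),
                 d)$y
  fast <- approx(s$displacement[s$velocity == 4],
                 moving_average(s$t[s$velocity == 4], s$force[s$velocity == 4]),
                 d)$y
  expect_true(all(fast >= slow))
})

test_that("creep displacement is inversely ordered in b1", {
  cr <- run_creep(b1_values = c(50, 200), duration = 30,
                  config = solver_config(dt = 0.02, iterations = 5),
                  force = 20, edge = 20, divisions = 2)
  s <- cr$series
  at <- function(b1, t) approx(s$t[s$b1 == b1], s$displacement[s$b1 == b1], t)$y
  for (t in c(5, 10, 20)) expect_gte(at(50, t), at(200, t))
  expect_equal(unique(s$b1), c(50, 200))
})

test_that("zero creep force produces zero displacement", {
  cr <- run_creep(b1_values = 100, duration = 5, force = 0,
                  config = solver_config(dt = 0.02, iterations = 5),
                  edge = 20, divisions = 2)
  expect_lt(max(cr$series$displacement), 1e-9)
})

test_that("relaxation force decays after the ramp and b1 = 0 stays elastic", {
  sr <- run_stress_relaxation(b1_values = c(0, 200), ramp_displacement = 4,
                              ramp_time = 0.25, hold_time = 1.5,
                              config = small_cfg, edge = 20, divisions = 2)
  s <- sr$series
  at <- function(b1, t) approx(s$t[s$b1 == b1], s$force_smooth[s$b1 == b1], t)$y
  # viscous model relaxes
  expect_lt(at(200, 1.7), at(200, 0.45))
  # pure elastic (b1 = 0) settles to a constant force
  expect_equal(at(0, 1.2), at(0, 1.7), tolerance = 0.02)
})

test_that("experiment runners are deterministic", {
  a <- run_nonlinearity(velocities = 3, max_displacement = 3,
                        config = small_cfg, edge = 20, divisions = 2)
  b <- run_nonlinearity(velocities = 3, max_displacement = 3,
                        config = small_cfg, edge = 20, divisions = 2)
  expect_identical(a$series, b$series)
})

test_that("volume runners report the ratio series from 1.0 at start", {
  vt <- run_volume_tests("cantilever", duration = 0.2,
                         config = solver_config(dt = 0.01, iterations = 5,
                                                gravity = c(0, 0, -9810)))
  expect_equal(vt$series$volume_ratio[1], 1, tolerance = 1e-4)
  expect_true(all(diff(vt$series$t) > 0))
})

test_that("an uncrushed cube reports near-zero deviation and no divergence", {
  st <- run_stability(crush_fraction = 0.999, crush_time = 0.05,
                      hold_time = 0.05, recovery_time = 0.3,
                      config = small_cfg, edge = 20, divisions = 2)
  expect_false(st$diverged)
  expect_true(st$recovered)
  expect_lt(st$final_deviation, 0.2)
})

test_that("Q statistic sums matched node distances and is symmetric", {
  a <- rbind(c(0, 0, 0), c(1, 1, 1))
  b <- a + matrix(c(1, 0, 0, 1, 0, 0), 2, 3, byrow = TRUE)
  expect_equal(q_statistic(a, a), 0)
  expect_equal(q_statistic(a, b), 2)
  expect_equal(q_statistic(b, a), q_statistic(a, b))
  expect_error(q_statistic(a, rbind(c(0, 0, 0))), "invalid-argument")
})
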