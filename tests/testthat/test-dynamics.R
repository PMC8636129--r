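test_that("corner starts give constant, immediately converged trajectories", {
  p <- fix1()
  for (corner in list(c(0, 0), c(1, 1))) {
    tr <- integrate_trajectory(p, corner, t_max = 10)
    expect_true(tr$converged)
    expect_equal(unname(tr$limit), corner)
    expect_true(all(tr$states[, 1] == corner[1]))
    expect_true(all(tr$states[, 2] == corner[2]))
  }
})

test_that("trajectory structure is well-formed", {
  tr <- integrate_trajectory(fix2(), c(0.3, 0.3), t_max = 200)
  expect_true(all(diff(tr$times) > 0))
  expect_true(all(tr$states >= 0 & tr$states <= 1))
})

test_that("the flow reaches the regime's stable profile from the centre", {
  # unique-attractor regimes
  lr1 <- long_run_state(fix1(), c(0.5, 0.5))
  expect_true(lr1$decided)
  expect_equal(lr1$state, c(0, 1))
  lr3 <- long_run_state(fix3(), c(0.5, 0.5))
  expect_true(lr3$decided)
  expect_equal(lr3$state, c(1, 1))
  # bistable regime: the two sides of the separatrix reach different corners
  expect_equal(long_run_state(fix2(), c(0.1, 0.9))$state, c(0, 1))
  expect_equal(long_run_state(fix2(), c(0.9, 0.1))$state, c(1, 0))
})

test_that("adaptive integrator agrees with a fixed-step Euler oracle", {
  p <- fix2()
  init <- c(0.3, 0.3)
  tr <- integrate_trajectory(p, init, t_max = 10, n_out = 2L)
  adaptive_end <- tr$states[nrow(tr$states), ]
  euler_end <- euler_trajectory(p, init, t_end = 10, h = 1e-3)
  expect_equal(unname(adaptive_end), euler_end, tolerance = 1e-4)
})

test_that("trajectories stay inside the unit square for random games", {
  set.seed(404)
  for (i in 1:50) {
    p <- random_params()
    init <- runif(2, 0.05, 0.95)
    tr <- integrate_trajectory(p, init, t_max = 500)
    expect_true(all(tr$states >= 0 & tr$states <= 1))
  }
})

test_that("distance to a stable corner is non-increasing near that corner", {
  cases <- list(list(p = fix1(), corner = c(0, 1), init = c(0.04, 0.96)),
                list(p = fix3(), corner = c(1, 1), init = c(0.96, 0.97)))
  for (cs in cases) {
    tr <- integrate_trajectory(cs$p, cs$init, t_max = 2000, n_out = 800L)
    d <- sqrt((tr$states[, 1] - cs$corner[1])^2 +
              (tr$states[, 2] - cs$corner[2])^2)
    expect_true(all(diff(d) <= 1e-12))
  }
})

test_that("flow limits agree with the regime classifier on random games", {
  set.seed(505)
  # scaled down from a larger sweep: 8 parameter sets per regime, 3 starts
  for (regime in c(1L, 3L)) {
    sets <- sample_regime_parameters(regime, n = 8, seed = 500 + regime)
    target <- if (regime == 1L) c(0, 1) else c(1, 1)
    for (p in sets) {
      for (k in 1:3) {
        lr <- long_run_state(p, runif(2, 0.05, 0.95))
        expect_true(lr$decided)
        expect_equal(lr$state, target)
      }
    }
  }
  sets2 <- sample_regime_parameters(2L, n = 8, seed = 502)
  for (p in sets2) {
    lr <- long_run_state(p, runif(2, 0.05, 0.95))
    expect_true(lr$decided)
    expect_true(identical(lr$state, c(0, 1)) || identical(lr$state, c(1, 0)))
  }
})

test_that("vector-field grids carry the replicator field on the lattice", {
  g2 <- vector_field_grid(fix1(), 2L)
  expect_equal(nrow(g2), 4L)
  expect_true(all(g2$dx == 0 & g2$dy == 0))  # corners only
  g21 <- vector_field_grid(fix1(), 21L)
  expect_equal(nrow(g21), 441L)
  mid <- g21[g21$x == 0.5 & g21$y == 0.5, ]
  expect_equal(c(mid$dx, mid$dy), c(0.000625, 0.006875), tolerance = 1e-12)
  # bistable fixture: on the y = 0.9 row the share probability always falls
  gb <- vector_field_grid(fix2(), 21L)
  row <- gb[abs(gb$y - 0.9) < 1e-9 & gb$x > 0 & gb$x < 1, ]
  expect_true(all(row$dx < 0))
  expect_error(vector_field_grid(fix1(), 1L), "resolution")
})

test_that("trajectory and grid CSV exports round-trip exactly", {
  tr <- integrate_trajectory(fix1(), c(0.5, 0.5), t_max = 50, n_out = 20L)
  f <- tempfile(fileext = ".csv")
  export_csv(tr, f)
  back <- read.csv(f)
  expect_identical(names(back), c("t", "x", "y"))
  expect_equal(back$x, unname(tr$states[, 1]), tolerance = 0)
  g <- vector_field_grid(fix1(), 5L)
  export_csv(g, f2 <- tempfile(fileext = ".csv"))
  backg <- read.csv(f2)
  expect_identical(names(backg), c("x", "y", "dx", "dy"))
  expect_equal(backg$dx, g$dx, tolerance = 0)
  unlink(c(f, f2))
})
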