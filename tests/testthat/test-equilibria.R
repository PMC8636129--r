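test_that("interior rest point follows from the replicator factors", {
  # bistable fixture: both bracketed factors vanish at 10/13
  ip <- interior_rest_point(fix2())
  expect_equal(unname(ip$point), c(10 / 13, 10 / 13), tolerance = 1e-12)
  expect_true(ip$inside)
  # the flow really vanishes there
  expect_equal(max(abs(replicator_rhs(fix2(), ip$point))), 0,
               tolerance = 1e-12)
  # printed-variant formulas have the opposite-sign denominator and land
  # outside the square on the same fixture
  ipp <- interior_rest_point(fix2(), printed = TRUE)
  expect_equal(unname(ipp$point), -c(10 / 13, 10 / 13), tolerance = 1e-12)
  expect_false(ipp$inside)
  # degenerate denominator: (gamma-1)C == (alpha-1)L
  pd <- game_params(1, 0.2, 0.1, 1.5, 0.5, 2)
  ipd <- interior_rest_point(pd)
  expect_true(ipd$degenerate)
  expect_null(ipd$point)
})

test_that("equilibrium enumeration returns corners always, interior when inside", {
  eq2 <- enumerate_equilibria(fix2())
  expect_length(eq2, 5L)
  locs <- t(vapply(eq2, function(e) e$location, numeric(2)))
  expect_equal(locs[5, ], c(x = 10 / 13, y = 10 / 13), tolerance = 1e-12)
  # candidate outside (0,1): fix1 gives x = 0.1/0.09 > 1
  expect_length(enumerate_equilibria(fix1()), 4L)
  # candidate negative under fix3
  expect_length(enumerate_equilibria(fix3()), 4L)
  # degenerate interior flagged
  eqd <- enumerate_equilibria(game_params(1, 0.2, 0.1, 1.5, 0.5, 2))
  expect_true(attr(eqd, "interior_degenerate"))
})

test_that("Jacobian closed forms match the finite-difference oracle", {
  set.seed(202)
  for (i in 1:200) {
    p <- random_params()
    for (k in 1:5) {
      s <- runif(2)
      expect_equal(unname(jacobian_at(p, s)), fd_jacobian(p, s),
                   tolerance = 1e-6)
    }
  }
})

test_that("corner Jacobians are diagonal with the known entries", {
  J <- jacobian_at(fix1(), c(0, 1))
  expect_equal(unname(J), matrix(c(-0.02, 0, 0, -0.05), 2), tolerance = 1e-12)
  # generic corner structure: off-diagonals vanish exactly
  for (i in 1:20) {
    p <- random_params()
    for (corner in list(c(0, 0), c(0, 1), c(1, 0), c(1, 1))) {
      Jc <- jacobian_at(p, corner)
      expect_identical(Jc[1, 2], 0)
      expect_identical(Jc[2, 1], 0)
    }
    # (0,0) always has c11 = (alpha-1)*beta*V > 0
    expect_gt(jacobian_at(p, c(0, 0))[1, 1], 0)
  }
  # interior rest point has zero diagonal
  Ji <- jacobian_at(fix2(), interior_rest_point(fix2())$point)
  expect_equal(Ji[1, 1], 0, tolerance = 1e-12)
  expect_equal(Ji[2, 2], 0, tolerance = 1e-12)
})

test_that("stability classification follows the eigenvalue signs", {
  rep01 <- classify_equilibrium(fix1(), c(0, 1))
  expect_equal(sort(Re(rep01$eigenvalues)), c(-0.05, -0.02), tolerance = 1e-12)
  expect_identical(rep01$stability, "stable")
  # interior point of the bistable fixture is a saddle
  repi <- classify_equilibrium(fix2(), interior_rest_point(fix2())$point)
  expect_identical(repi$stability, "saddle")
  expect_lt(prod(Re(repi$eigenvalues)), 0)
  # non-rest-points are rejected
  expect_error(classify_equilibrium(fix1(), c(0.5, 0.5)), "not a rest point")
  # (0,0) is never stable
  for (i in 1:20) {
    p <- random_params()
    expect_false(classify_equilibrium(p, c(0, 0))$stability == "stable")
  }
})

test_that("the three benchmark fixtures classify into their regimes", {
  r1 <- classify_regime(fix1())
  expect_identical(r1$regime, 1L)
  expect_equal(r1$stable_set, list(c(0, 1)))
  r2 <- classify_regime(fix2())
  expect_identical(r2$regime, 2L)
  expect_equal(r2$stable_set, list(c(0, 1), c(1, 0)))
  r3 <- classify_regime(fix3())
  expect_identical(r3$regime, 3L)
  expect_equal(r3$stable_set, list(c(1, 1)))
})

test_that("regime boundaries are reported degenerate, not forced", {
  # alpha*L == gamma*C exactly: boundary between regimes 1 and 2
  p <- game_params(1, 0.2, 0.1, 1.05, 0.5, 2.1)
  expect_equal(p$alpha * p$L, p$gamma * p$C, tolerance = 1e-15)
  expect_identical(classify_regime(p)$regime, "degenerate_or_other")
})

test_that("regime-predicted stable sets match per-point classification", {
  set.seed(303)
  for (regime in 1:3) {
    sets <- sample_regime_parameters(regime, n = 15, seed = 300 + regime)
    for (p in sets) {
      reg <- classify_regime(p)
      expect_identical(reg$regime, regime)
      stable_corners <- Filter(function(e)
        e$kind == "corner" && e$stability == "stable",
        enumerate_equilibria(p))
      locs <- lapply(stable_corners, function(e) unname(e$location))
      expect_setequal(lapply(locs, paste, collapse = ","),
                      lapply(reg$stable_set, paste, collapse = ","))
    }
  }
})

test_that("regime label and stability classes are invariant in beta", {
  base <- unclass(fix2())
  for (beta in c(0.1, 0.5, 0.9)) {
    base$beta <- beta
    p <- do.call(game_params, base)
    expect_identical(classify_regime(p)$regime, 2L)
    stab <- vapply(enumerate_equilibria(p), function(e) e$stability, "")
    expect_identical(stab, c("unstable", "stable", "stable", "unstable",
                             "saddle"))
    # equilibrium locations do not move with beta
    expect_equal(enumerate_equilibria(p)[[5]]$location,
                 c(x = 10 / 13, y = 10 / 13), tolerance = 1e-12)
  }
})
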