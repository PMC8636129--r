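test_that("welfare totals match the closed forms on the benchmark fixtures", {
  w1 <- total_welfare_profiles(fix1())
  expect_equal(unname(w1$totals), c(1.06, 1.05, 1.1, 1.0), tolerance = 1e-12)
  expect_identical(w1$optimum, "not_disclose")
  w3 <- total_welfare_profiles(fix3())
  expect_equal(unname(w3$totals["share_disclose"]), 1.21, tolerance = 1e-12)
  expect_identical(w3$optimum, "share_disclose")
})

test_that("welfare is independent of the split parameter beta", {
  base <- list(V = 1.5, L = 0.4, C = 0.2, alpha = 1.2, gamma = 1.7)
  w_lo <- total_welfare_profiles(do.call(game_params, c(base, beta = 0.2)))
  w_hi <- total_welfare_profiles(do.call(game_params, c(base, beta = 0.8)))
  expect_identical(w_lo$totals, w_hi$totals)
  expect_identical(w_lo$optimum, w_hi$optimum)
})

test_that("exact welfare ties are reported as ties", {
  # alpha*V == (V+L)-C: V=1, L=0.2, C=0.1, alpha=1.1 -> both 1.1
  p <- game_params(1, 0.2, 0.1, 1.1, 0.5, 3.5)
  w <- total_welfare_profiles(p)
  expect_true(w$tie)
  expect_setequal(w$optimum, c("share_not", "not_disclose"))
})

test_that("threshold rule agrees with the direct argmax", {
  # regime 1: (alpha-1) = 0.05 < (L-C)/V = 0.1 favours (not share, disclose)
  o1 <- social_optimum(fix1())
  expect_identical(o1$threshold$favours, "not_disclose")
  expect_true(o1$threshold$agrees_with_argmax)
  expect_identical(o1$optimum, "not_disclose")
  # other branch: alpha = 1.15 makes alpha*V = 1.15 beat (V+L)-C = 1.1
  p <- game_params(1, 0.2, 0.1, 1.15, 0.5, 2.5)
  w <- total_welfare_profiles(p)
  expect_gt(w$totals["share_not"], w$totals["not_disclose"])
  # regime 2 case with the not-share side optimal
  o2 <- social_optimum(fix2())
  expect_identical(o2$regime, 2L)
  expect_true(o2$threshold$agrees_with_argmax)
})

test_that("growth condition is equivalent to the welfare comparison", {
  # (alpha-1)beta(V+L) < (gamma-1)beta C  <=>  alpha(V+L)-gamma C < (V+L)-C
  set.seed(909)
  for (i in 1:100) {
    p <- random_params()
    lhs <- (p$alpha - 1) * p$beta * (p$V + p$L) < (p$gamma - 1) * p$beta * p$C
    w <- total_welfare_profiles(p)$totals
    rhs <- w["share_disclose"] < w["not_disclose"]
    expect_identical(lhs, unname(rhs))
  }
})

test_that("regime-1 games order welfare as U10 > U01 > U11", {
  sets <- sample_regime_parameters(1L, n = 20, seed = 1001)
  for (p in sets) {
    # regime 1 forces (alpha-1) < (L-C)/V, so the ordering always holds
    expect_lt(p$alpha - 1, (p$L - p$C) / p$V)
    w <- total_welfare_profiles(p)$totals
    expect_gt(w["not_disclose"], w["share_not"])
    expect_gt(w["share_not"], w["not_not"])
  }
})

test_that("evolutionary outcome and social optimum align inside the regimes", {
  a1 <- alignment_report(fix1())
  expect_true(a1$aligned)
  expect_identical(a1$optimum, "not_disclose")
  a3 <- alignment_report(fix3())
  expect_true(a3$aligned)
  # the benchmark bistable fixture ties exactly (alpha*V = (V+L)-C = 1.1),
  # so both stable corners are optimal there
  a2 <- alignment_report(fix2())
  expect_true(a2$aligned)
  expect_equal(nrow(a2$per_corner), 2L)
  expect_equal(sum(a2$per_corner$is_optimum), 2L)
  expect_equal(sum(a2$per_corner$basin_probability), 1, tolerance = 1e-12)
  # an untied regime-2 set names exactly one optimal corner
  a2b <- alignment_report(game_params(1, 0.2, 0.1, 1.05, 0.5, 2.3))
  expect_identical(a2b$regime, 2L)
  expect_equal(sum(a2b$per_corner$is_optimum), 1L)
  expect_true(a2b$per_corner$is_optimum[a2b$per_corner$x == 0])
  # degenerate parameter sets are refused
  expect_error(alignment_report(game_params(1, 0.2, 0.1, 1.05, 0.5, 2.1)),
               "degenerate")
})

test_that("alignment holds across all three regimes by construction", {
  # the regime inequalities pin the optimum inside the stable set: regime 1
  # implies (alpha-1)V < L-C, regime 2's two contenders are its two stable
  # corners, and regime 3's conditions make (share, disclose) dominant
  for (regime in 1:3) {
    sets <- sample_regime_parameters(regime, n = 10, seed = 1100 + regime)
    for (p in sets) {
      rep <- alignment_report(p)
      expect_true(rep$aligned)
    }
  }
})
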