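test_that("sampled parameters come from the design sets, deterministically", {
  set.seed(101)
  draws <- replicate(200, sample_parameters(), simplify = FALSE)
  r1s <- vapply(draws, `[[`, 0, "r1")
  r2s <- vapply(draws, `[[`, 0, "r2")
  q1s <- vapply(draws, `[[`, 0, "q1")
  q2s <- vapply(draws, `[[`, 0, "q2")
  expect_true(all(r1s %in% seq(0.55, 0.90, by = 0.05)))
  expect_true(all(r2s %in% seq(0.20, 0.55, by = 0.05)))
  expect_true(all(q1s %in% (c(1, 1.5, 2, 2.5) * 1e-5)))
  expect_true(all(q2s %in% (c(2, 2.5, 3) * 1e-5)))
  # construction guarantees r1 >= r2, and the delta ranges follow
  expect_true(all(r1s - r2s >= 0 & r1s - r2s <= 0.70))
  expect_true(all(q1s - q2s >= -2.0e-5 - 1e-12 & q1s - q2s <= 0.5e-5 + 1e-12))
  set.seed(77)
  a <- sample_parameters()
  set.seed(77)
  b <- sample_parameters()
  expect_identical(a, b)
})

test_that("zero-catch logistic recursion converges to carrying capacity", {
  B <- schaefer_recursion(1.5e6, 0.7, 2e6, 0, 200)
  expect_lt(abs(tail(B, 1) - 2e6) / 2e6, 1e-3)
  expect_true(all(diff(B) > -1e-9))      # monotone approach from below
})

test_that("constant-effort deterministic run hits the closed-form equilibrium", {
  for (case in list(c(r = 0.7, q = 2e-5), c(r = 0.55, q = 1e-5),
                    c(r = 0.9, q = 2.5e-5))) {
    p <- population_parameters(case["r"], case["r"], case["q"], case["q"])
    s <- simulate_series(p, stochastic = FALSE)
    Bstar <- p$K * (1 - case["q"] * p$effort_mean / case["r"])
    expect_lt(abs(tail(s$biomass, 1) - Bstar) / Bstar, 5e-4)  # 4 sig figs
  }
})

test_that("series respects the exact Schaefer recursion and CPUE identity", {
  set.seed(5)
  p <- sample_parameters()
  s <- simulate_series(p)
  expect_equal(nrow(s), 64L)
  expect_true(all(is.finite(s$biomass)) && all(s$biomass > 0))
  expect_equal(s$cpue * s$effort, s$catch, tolerance = 1e-12)
  r_of <- ifelse(s$year >= p$change_year, p$r2, p$r1)
  for (t in 2:nrow(s)) {
    expected <- s$biomass[t - 1] +
      r_of[t] * s$biomass[t - 1] * (1 - s$biomass[t - 1] / p$K) -
      s$catch[t - 1]
    expect_equal(s$biomass[t], expected, tolerance = 1e-10)
  }
})

test_that("identical seeds give bit-identical series", {
  p <- population_parameters(0.8, 0.3, 1.5e-5, 2.5e-5)
  set.seed(42)
  a <- simulate_series(p)
  set.seed(42)
  b <- simulate_series(p)
  expect_identical(a, b)
})

test_that("a growth-rate drop depresses late-period biomass", {
  p <- population_parameters(0.8, 0.3, 2e-5, 2e-5, catch_noise_var = 0)
  s <- simulate_series(p, stochastic = FALSE)
  expect_lt(mean(s$biomass[s$year %in% 40:63]),
            mean(s$biomass[s$year %in% 8:31]))
})

test_that("with no regime change the two periods are indistinguishable", {
  set.seed(2024)
  pvals <- replicate(40, {
    p <- population_parameters(0.55, 0.55, 2e-5, 2e-5)
    s <- simulate_series(p)
    suppressWarnings(
      stats::ks.test(s$cpue[s$year < 32], s$cpue[s$year >= 32])$p.value)
  })
  expect_lte(mean(pvals < 0.01), 0.15)   # rejects about at (small) nominal rate
})

test_that("collapse regimes stay strictly positive via the catch clamp", {
  set.seed(9)
  for (i in 1:5) {
    p <- population_parameters(0.9, 0.2, 1e-5, 3e-5, catch_noise_var = 0.1)
    s <- simulate_series(p)
    expect_true(all(s$biomass > 0))
  }
})

test_that("stabilization segment is available on request", {
  set.seed(3)
  p <- sample_parameters()
  s <- simulate_series(p, include_stabilization = TRUE)
  stab <- attr(s, "stabilization")
  expect_equal(nrow(stab), 32L)
  expect_true(all(stab$year < 0))
})
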