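fake_fit <- function(rhat, ess) {
  structure(list(summary = data.frame(
    param = paste0("p", seq_along(rhat)),
    mean = 0, sd = 1, lower = -1, upper = 1,
    ess = ess, rhat = rhat, scalar = TRUE)), class = "scenario_fit")
}

test_that("convergence detector applies the scale-reduction and ESS rules", {
  expect_true(check_convergence(fake_fit(rep(1.00, 4), rep(4000, 4))))
  expect_false(check_convergence(fake_fit(c(1.00, 1.30, 1.00), rep(4000, 3))))
  expect_false(check_convergence(fake_fit(rep(1.00, 3), c(4000, 50, 4000))))
})

test_that("split-chain scale reduction flags a bimodal non-mixing target", {
  set.seed(4)
  well <- cbind(rnorm(600), rnorm(600))
  expect_lt(split_rhat(well), 1.05)
  # two chains stuck in separated modes of a mixture
  stuck <- cbind(rnorm(600, 0, 0.3), rnorm(600, 8, 0.3))
  r <- split_rhat(stuck)
  expect_gt(r, 1.05)
  fit <- fake_fit(c(1.0, r), c(1000, 1000))
  expect_false(check_convergence(fit))
})

test_that("fits are reproducible under the same seed", {
  set.seed(12)
  p <- sample_parameters()
  s <- simulate_series(p)
  f1 <- fit_scenario(s, scenario_spec(3, change_year = 32), chains = 2,
                     draws = 300, warmup = 200, adapt = 200, seed = 5)
  f2 <- fit_scenario(s, scenario_spec(3, change_year = 32), chains = 2,
                     draws = 300, warmup = 200, adapt = 200, seed = 5)
  expect_equal(f1$summary$mean, f2$summary$mean, tolerance = 1e-12)
  expect_equal(f1$summary$ess, f2$summary$ess, tolerance = 1e-12)
})

test_that("posteriors of r and q are invariant to rescaling catch and K", {
  set.seed(13)
  p <- sample_parameters()
  s <- simulate_series(p)
  s10 <- s
  s10$catch <- s$catch * 10
  s10$cpue <- s10$catch / s10$effort
  fa <- fit_scenario(s, scenario_spec(3, change_year = 32, K_assumed = 2e6),
                     chains = 2, draws = 800, warmup = 400, adapt = 400,
                     seed = 7)
  fb <- fit_scenario(s10, scenario_spec(3, change_year = 32, K_assumed = 2e7),
                     chains = 2, draws = 800, warmup = 400, adapt = 400,
                     seed = 7)
  for (par in c("r[1]", "r[2]", "q[1]", "q[2]")) {
    ma <- fa$summary$mean[fa$summary$param == par]
    mb <- fb$summary$mean[fb$summary$param == par]
    expect_equal(ma, mb, tolerance = 0.05)
  }
})

test_that("with no regime change, the single-regime fit matches the two-regime one", {
  set.seed(14)
  p <- population_parameters(0.55, 0.55, 2e-5, 2e-5)
  s <- simulate_series(p)
  f1 <- fit_scenario(s, scenario_spec(1), chains = 2, draws = 800,
                     warmup = 400, adapt = 400, seed = 3)
  f3 <- fit_scenario(s, scenario_spec(3, change_year = 32), chains = 2,
                     draws = 800, warmup = 400, adapt = 400, seed = 3)
  r_hat <- f1$summary$mean[f1$summary$param == "r"]
  s3 <- f3$summary
  expect_gte(r_hat, s3$lower[s3$param == "r[1]"] - 1e-9)
  expect_lte(r_hat, s3$upper[s3$param == "r[1]"] + 1e-9)
  expect_gte(r_hat, s3$lower[s3$param == "r[2]"] - 1e-9)
  expect_lte(r_hat, s3$upper[s3$param == "r[2]"] + 1e-9)
})

test_that("scenario specifications are validated", {
  expect_error(scenario_spec(4), "must be 1, 2 or 3")
  expect_error(scenario_spec(2), "require change_year")
  expect_error(scenario_spec(1, change_year = 30), "ignores the change point")
  expect_error(scenario_spec(3, change_year = 32, K_assumed = -1), "positive")
})
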