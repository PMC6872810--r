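test_that("relative bias is plain arithmetic and rejects zero truth", {
  expect_equal(relative_bias(0.6, 0.5), 0.2)
  expect_equal(relative_bias(33, 32), 0.03125)
  expect_equal(relative_bias(7, 7), 0)
  expect_equal(relative_bias(0.6, 0.5, percent = TRUE), 20)
  expect_error(relative_bias(1, 0), "zero truth")
})

test_that("delta bins follow the half-open printed boundaries", {
  drb <- joinpointSPM:::dr_bin(c(0, 0.20, 0.21, 0.45, 0.46, 0.70))
  expect_equal(as.integer(drb), c(1L, 1L, 2L, 2L, 3L, 3L))
  dqb <- joinpointSPM:::dq_bin(c(-2e-5, -1.5e-5, -1.4e-5, -5e-6, -4.9e-6, 0.5e-5))
  expect_equal(as.integer(dqb), c(1L, 1L, 2L, 2L, 3L, 3L))
})

make_records <- function() {
  data.frame(
    sim_id = 1:4,
    r1 = c(0.8, 0.8, 0.6, 0.6), r2 = c(0.3, 0.3, 0.5, 0.5),
    q1 = rep(2e-5, 4), q2 = rep(2e-5, 4),
    delta_r = c(0.5, 0.5, 0.1, 0.1), delta_q = rep(0, 4),
    dr_bin = c("(0.45,0.70]", "(0.45,0.70]", "[0.00,0.20]", "[0.00,0.20]"),
    dq_bin = rep(">-5e-06", 4),
    t1_star = c(31, 33, 30, 36), t2_star = c(38, 40, 39, 44),
    t_star = c(31, 33, 30, 36), transition = c(7, 7, 9, 8),
    n_init_converged = 5L,
    s1_r1_bias = c(0.10, -0.10, 0, 0),
    s1_q1_bias = c(0.2, 0.2, 0.1, 0.1)
  )
}

test_that("bias tables use sample sd and report empty bins as missing", {
  sm <- summarize_tables(make_records())
  tab <- sm$table_r1
  big <- tab[tab$bin == "(0.45,0.70]" & tab$scenario == 1, ]
  expect_equal(big$mean_pct, 0)
  expect_equal(big$sd_pct, 100 * sd(c(0.10, -0.10)))   # 14.14..., n-1 denom
  empty <- tab[tab$bin == "(0.20,0.45]" & tab$scenario == 1, ]
  expect_true(is.na(empty$mean_pct))
  # scenario 2 was never fit: its cells must be missing, not zero
  expect_true(all(is.na(tab$mean_pct[tab$scenario == 2])))
})

test_that("bin-weighted means aggregate to the overall mean", {
  sm <- summarize_tables(make_records())
  tab <- sm$table_q1[sm$table_q1$scenario == 1, ]
  tab <- tab[!is.na(tab$mean_pct), ]
  overall <- sum(tab$mean_pct * tab$n) / sum(tab$n)
  expect_equal(overall, 100 * mean(make_records()$s1_q1_bias))
})

test_that("joinpoint summary statistics match direct computation", {
  r <- make_records()
  sm <- summarize_tables(r)
  expect_equal(sm$t1_mean, mean(r$t1_star))
  expect_equal(sm$t1_var, var(r$t1_star))
  expect_equal(sm$transition_mean, mean(r$transition))
  rb <- (r$t1_star - 32) / 32
  expect_equal(sm$t1_bias_mean, mean(rb))
  expect_equal(sm$t1_bias_ci,
               mean(rb) + c(-1, 1) * 1.96 * sd(rb) / sqrt(length(rb)))
  expect_equal(sm$t1_var_ratio_small_dr,
               var(r$t1_star[r$delta_r < 0.1]) / var(r$t1_star[r$delta_r >= 0.1]))
})

test_that("studies are reproducible from the master seed", {
  a <- run_study(n_sims = 8, seed = 123)
  b <- run_study(n_sims = 8, seed = 123)
  expect_identical(a$records, b$records)
  expect_equal(a$summary$t1_mean, b$summary$t1_mean)
})

test_that("a changeless deterministic world rejects every simulation", {
  expect_error(
    run_study(n_sims = 2, seed = 1, max_reject_factor = 4,
              sets = list(r1 = 0.55, r2 = 0.55, q1 = 2e-5, q2 = 2e-5),
              stochastic = FALSE, catch_noise_var = 0,
              stabilization_years = 300),
    "rejection ceiling")
})

test_that("study output files round-trip", {
  out <- file.path(tempdir(), "jps-study-out")
  st <- run_study(n_sims = 5, seed = 9, out_dir = out)
  expect_true(file.exists(file.path(out, "records.csv")))
  expect_true(file.exists(file.path(out, "summary.json")))
  expect_true(file.exists(file.path(out, "run_manifest.json")))
  rec <- read.csv(file.path(out, "records.csv"))
  expect_equal(nrow(rec), 5L)
  man <- jsonlite::read_json(file.path(out, "run_manifest.json"))
  expect_equal(man$seed, 9L)
  unlink(out, recursive = TRUE)
})
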