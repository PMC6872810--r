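# Brute-force RSS grid search over breakpoint pairs: the independent
# oracle the segmented fitter is checked against. Deliberately naive.
grid_rss_min <- function(year, y, step = 0.25, min_sep = 2) {
  ps <- seq(min(year) + 2, max(year) - 2, by = step)
  best <- c(NA_real_, NA_real_, Inf)
  for (p1 in ps) {
    for (p2 in ps[ps >= p1 + min_sep]) {
      X <- cbind(1, year, pmax(year - p1, 0), pmax(year - p2, 0))
      r <- sum(stats::.lm.fit(X, y)$residuals^2)
      if (r < best[3L]) best <- c(p1, p2, r)
    }
  }
  list(psi = best[1:2], rss = best[3L])
}

# random continuous piecewise-linear instance with two kinks
random_piecewise <- function(n = 30, noise_sd = 0.5) {
  year <- 0:(n - 1)
  br <- sort(stats::runif(2, min(year) + 4, max(year) - 4))
  while (diff(br) < 6) br <- sort(stats::runif(2, min(year) + 4, max(year) - 4))
  b0 <- stats::runif(1, 5, 20)
  b1 <- stats::runif(1, -0.5, 0.5)
  d1 <- sample(c(-1, 1), 1) * stats::runif(1, 1, 3)
  d2 <- -d1 * stats::runif(1, 0.5, 1.5)
  y <- b0 + b1 * year + d1 * pmax(year - br[1], 0) + d2 * pmax(year - br[2], 0)
  list(year = year, y = y + stats::rnorm(n, 0, noise_sd), breaks = br,
       y_clean = y)
}

# canonical low-noise world used by several parameter-recovery checks
recovery_params <- function() {
  population_parameters(0.80, 0.30, 1.5e-5, 2.5e-5, catch_noise_var = 1e-4)
}
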