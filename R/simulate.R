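#' Deterministic Schaefer recursion
#'
#' Iterates the discrete logistic (Schaefer) biomass update
#' `B[t+1] = B[t] + r * B[t] * (1 - B[t] / K) - C[t]`
#' for a fixed growth rate and a prescribed catch sequence. This is the
#' noise-free backbone of the simulator, exposed for closed-form checks:
#' with zero catch the trajectory converges to `K`; with catch proportional
#' to biomass, `C[t] = q * E * B[t]`, the fixed point is
#' `B* = K * (1 - q * E / r)`.
#'
#' @param B0 Starting biomass.
#' @param r Growth rate per year.
#' @param K Carrying capacity.
#' @param catch Vector of absolute removals per year, recycled to length
#'   `n` (so a scalar gives constant catch).
#' @param n Number of annual steps.
#' @return Numeric vector of length `n + 1` of biomass values, starting
#'   at `B0`.
#' @export
#' @examples
#' tail(schaefer_recursion(1.5e6, 0.7, 2e6, 0, 200), 1)  # ~ K
schaefer_recursion <- function(B0, r, K, catch, n) {
  catch <- rep_len(catch, n)
  B <- numeric(n + 1L)
  B[1L] <- B0
  for (t in seq_len(n)) {
    B[t + 1L] <- B[t] + r * B[t] * (1 - B[t] / K) - catch[t]
    if (!is.finite(B[t + 1L])) stop("non-finite biomass at step ", t)
  }
  B
}

#' Simulate a surplus-production series with a regime change
#'
#' Generates yearly biomass, effort, catch and CPUE from the Schaefer model
#' with a single structural change. The population is first run for
#' `params$stabilization_years` under (`r1`, `q1`), starting from `B0`, so
#' that it settles near its harvested equilibrium; the analyzed series then
#' restarts the clock at year 0 from the final stabilization biomass, runs
#' to `change_year - 1` under (`r1`, `q1`), and from `change_year` onward
#' under (`r2`, `q2`).
#'
#' Within each year the order of operations is: biomass updates from last
#' year's biomass and catch; effort `E_t` is drawn Poisson(`effort_mean`);
#' catch is `q_i * B_t * E_t * exp(e_t)` with `e_t ~ N(0, catch_noise_var)`
#' on the log scale; CPUE is `catch / effort`. If a realized catch would
#' drive next year's biomass non-positive it is truncated to 99% of the
#' maximum removal compatible with positive biomass, and the event is
#' counted in the `n_clamped` attribute.
#'
#' @param params A [population_parameters()] object.
#' @param stochastic If `FALSE`, effort is fixed at `effort_mean` (not drawn)
#'   and the log-scale catch noise is switched off, giving the deterministic
#'   skeleton of the model.
#' @param include_stabilization If `TRUE` the stabilization segment is
#'   attached as attribute `"stabilization"` (a data frame with negative
#'   year indices).
#' @return A data frame of class `spm_series` with columns `year` (0-based
#'   integer), `biomass`, `effort`, `catch`, `cpue`, plus attributes
#'   `params` and `n_clamped`.
#' @export
#' @examples
#' set.seed(7)
#' s <- simulate_series(population_parameters(0.8, 0.3, 1.5e-5, 2.5e-5))
#' head(s)
simulate_series <- function(params, stochastic = TRUE,
                            include_stabilization = FALSE) {
  stopifnot(inherits(params, "population_parameters"))
  n_stab <- params$stabilization_years
  n_ana <- params$n_years
  n_tot <- n_stab + n_ana
  K <- params$K

  # regime of each absolute year (1-based over stabilization + analyzed)
  analyzed_year <- seq_len(n_tot) - 1L - n_stab    # -n_stab .. n_ana-1
  regime <- ifelse(analyzed_year >= params$change_year, 2L, 1L)
  r_of <- c(params$r1, params$r2)
  q_of <- c(params$q1, params$q2)

  B <- E <- C <- numeric(n_tot)
  n_clamped <- 0L
  B[1L] <- params$B0
  for (t in seq_len(n_tot)) {
    if (t > 1L) {
      rt <- r_of[regime[t]]
      B[t] <- B[t - 1L] + rt * B[t - 1L] * (1 - B[t - 1L] / K) - C[t - 1L]
      if (!is.finite(B[t]) || B[t] <= 0)
        stop("non-positive or non-finite biomass at year ", analyzed_year[t])
    }
    E[t] <- if (stochastic) stats::rpois(1L, params$effort_mean) else params$effort_mean
    eps <- if (stochastic && params$catch_noise_var > 0)
      stats::rnorm(1L, 0, sqrt(params$catch_noise_var)) else 0
    C[t] <- q_of[regime[t]] * B[t] * E[t] * exp(eps)
    # keep next year's biomass strictly positive
    if (t < n_tot) {
      r_next <- r_of[regime[t + 1L]]
      cmax <- B[t] + r_next * B[t] * (1 - B[t] / K)
      if (C[t] >= cmax) {
        C[t] <- 0.99 * cmax
        n_clamped <- n_clamped + 1L
      }
    }
  }
  cpue <- ifelse(E > 0, C / E, NA_real_)

  idx <- (n_stab + 1L):n_tot
  out <- data.frame(year = analyzed_year[idx], biomass = B[idx],
                    effort = E[idx], catch = C[idx], cpue = cpue[idx])
  class(out) <- c("spm_series", "data.frame")
  attr(out, "params") <- params
  attr(out, "n_clamped") <- n_clamped
  if (include_stabilization) {
    attr(out, "stabilization") <-
      data.frame(year = analyzed_year[seq_len(n_stab)],
                 biomass = B[seq_len(n_stab)], effort = E[seq_len(n_stab)],
                 catch = C[seq_len(n_stab)], cpue = cpue[seq_len(n_stab)])
  }
  out
}
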