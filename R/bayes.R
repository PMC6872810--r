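#' Specify a surplus-production estimation scenario
#'
#' Three scenarios define how the change point enters the Bayesian
#' state-space surplus-production model: scenario 1 ignores it (a single
#' growth rate and catchability for the whole series); scenario 2 uses an
#' estimated change year (typically `t_star` from [estimate_joinpoint()]);
#' scenario 3 uses the true change year.
#'
#' @param scenario Integer 1, 2 or 3.
#' @param change_year 0-based change year used by the fit; required for
#'   scenarios 2 and 3, ignored (and must be absent) for scenario 1.
#' @param K_assumed Carrying capacity, treated as known.
#' @param prior Named list of prior settings; see [prior_config()].
#' @return A list of class `scenario_spec`.
#' @export
scenario_spec <- function(scenario, change_year = NULL, K_assumed = 2e6,
                          prior = prior_config()) {
  scenario <- as.integer(scenario)
  if (!scenario %in% 1:3) stop("scenario must be 1, 2 or 3")
  if (scenario == 1L && !is.null(change_year))
    stop("scenario 1 ignores the change point; do not supply change_year")
  if (scenario != 1L) {
    if (is.null(change_year)) stop("scenarios 2-3 require change_year")
    change_year <- as.integer(change_year)
  }
  if (!(K_assumed > 0)) stop("K_assumed must be positive")
  structure(list(scenario_id = scenario, change_year_used = change_year,
                 K_assumed = K_assumed, prior = prior),
            class = "scenario_spec")
}

#' Prior configuration for the state-space model
#'
#' Defaults: latent biomass proportions `P_t` truncated to
#' \[`P_lower`, `P_upper`\] = \[0.001, 1.2\] (the log stays well-defined
#' while slight overshoot of carrying capacity is allowed); vague
#' Gamma(0.01, 0.01) hyperpriors on the process and observation
#' *precisions*; growth rates uniform on (0.01, 1) — the upper bound keeps
#' the discrete logistic map well inside its stable regime; catchabilities
#' uniform on (-7, -3) on the log10 scale.
#'
#' @param P_lower,P_upper Truncation bounds for the latent proportions.
#' @param gamma_shape,gamma_rate Gamma hyperprior on each inverse variance.
#' @param r_lower,r_upper Uniform prior bounds for growth rates.
#' @param log10q_lower,log10q_upper Uniform prior bounds for log10
#'   catchability.
#' @return A named list.
#' @export
prior_config <- function(P_lower = 0.001, P_upper = 1.2,
                         gamma_shape = 0.01, gamma_rate = 0.01,
                         r_lower = 0.01, r_upper = 1,
                         log10q_lower = -7, log10q_upper = -3) {
  list(P_lower = P_lower, P_upper = P_upper,
       gamma_shape = gamma_shape, gamma_rate = gamma_rate,
       r_lower = r_lower, r_upper = r_upper,
       log10q_lower = log10q_lower, log10q_upper = log10q_upper)
}

# JAGS model: one regime (scenario 1) or two regimes indexed by reg[t].
jags_model_string <- function(two_regime) {
  decl <- if (two_regime) "for (i in 1:2) {" else "for (i in 1:1) {"
  paste0("
model {
  inv_sigma ~ dgamma(g_shape, g_rate)
  inv_tau ~ dgamma(g_shape, g_rate)
  sigma2 <- 1 / inv_sigma
  tau2 <- 1 / inv_tau
  ", decl, "
    r[i] ~ dunif(r_lo, r_hi)
    lq[i] ~ dunif(lq_lo, lq_hi)
    q[i] <- pow(10, lq[i])
  }
  P[1] ~ dlnorm(log(P0mu), inv_sigma) T(P_lo, P_hi)
  for (t in 2:T) {
    mu[t] <- max(P[t-1] + r", if (two_regime) "[reg[t]]" else "[1]",
    " * P[t-1] * (1 - P[t-1]) - C[t-1] / K, 1.0E-6)
    P[t] ~ dlnorm(log(mu[t]), inv_sigma) T(P_lo, P_hi)
  }
  for (t in 1:T) {
    I[t] ~ dlnorm(log(q", if (two_regime) "[reg[t]]" else "[1]",
    " * P[t] * K), inv_tau)
  }
}
")
}

#' Fit the Bayesian state-space surplus-production model
#'
#' Fits the surplus-production model in proportion/CPUE form by MCMC
#' (JAGS). The latent state is the biomass proportion `P_t = B_t / K`; its
#' prior is lognormal around the deterministic Schaefer update
#' `P_{t-1} + r_i P_{t-1} (1 - P_{t-1}) - C_{t-1} / K`, truncated to the
#' configured bounds; the observed CPUE `I_t` is lognormal around
#' `q_i P_t K`. The regime index `i` switches at the scenario's change
#' year (scenario 1 has a single regime). Carrying capacity is treated as
#' known. The inverse process and observation variances get Gamma
#' hyperpriors.
#'
#' Convergence is judged by [check_convergence()]: every structural
#' (non-latent) parameter needs split-chain scale reduction below 1.05 and
#' effective sample size of at least 100.
#'
#' @param series An `spm_series` or any data frame with `year`, `catch`,
#'   `effort`, `cpue` columns.
#' @param spec A [scenario_spec()].
#' @param chains,draws,warmup,adapt,thin MCMC settings: number of chains,
#'   kept draws per chain, burn-in iterations, adaptation iterations, and
#'   thinning interval.
#' @param seed Integer seed controlling the chain RNGs and initial values.
#' @param quiet Suppress JAGS progress output.
#' @return A list of class `scenario_fit` with elements `scenario`,
#'   `change_year_used`, `summary` (one row per monitored quantity: mean,
#'   sd, central 95% interval, effective sample size, split-chain scale
#'   reduction; `scalar` marks the structural parameters), `converged`,
#'   and `sampler` metadata.
#' @export
fit_scenario <- function(series, spec, chains = 2L, draws = 1000L,
                         warmup = 500L, adapt = 500L, thin = 1L,
                         seed = 1L, quiet = TRUE) {
  stopifnot(inherits(spec, "scenario_spec"))
  need <- c("year", "catch", "cpue")
  if (!all(need %in% names(series)))
    stop("series must have columns: ", paste(need, collapse = ", "))
  if (anyNA(series$cpue) || anyNA(series$catch))
    stop("catch and cpue must be present for all years")
  pr <- spec$prior
  n <- nrow(series)
  two <- spec$scenario_id != 1L
  reg <- if (two) ifelse(series$year < spec$change_year_used, 1L, 2L)
         else rep(1L, n)
  if (two && length(unique(reg)) != 2L)
    stop("change_year_used leaves an empty regime")
  K <- spec$K_assumed
  q_ref <- 10^stats::median(c(pr$log10q_lower, pr$log10q_upper))
  P0mu <- min(max(series$cpue[1L] / (q_ref * K), pr$P_lower * 5),
              pr$P_upper * 0.95)
  dat <- list(T = n, I = series$cpue, C = series$catch, K = K,
              P0mu = P0mu, P_lo = pr$P_lower, P_hi = pr$P_upper,
              g_shape = pr$gamma_shape, g_rate = pr$gamma_rate,
              r_lo = pr$r_lower, r_hi = pr$r_upper,
              lq_lo = pr$log10q_lower, lq_hi = pr$log10q_upper)
  if (two) dat$reg <- reg

  n_par <- if (two) 2L else 1L
  P_init <- pmin(pmax(series$cpue / (q_ref * K), pr$P_lower * 10),
                 pr$P_upper / 1.05)
  lq0 <- log10(stats::median(series$cpue) / (0.7 * K))
  lq0 <- min(max(lq0, pr$log10q_lower + 0.1), pr$log10q_upper - 0.1)
  r_spread <- seq(0.3, 0.9, length.out = chains)
  inits <- lapply(seq_len(chains), function(ch) {
    list(r = rep(r_spread[ch], n_par),
         lq = rep(lq0 + 0.1 * (ch - (chains + 1) / 2), n_par),
         P = P_init,
         .RNG.name = "base::Mersenne-Twister",
         .RNG.seed = as.integer(seed) + ch)
  })

  model <- rjags::jags.model(
    textConnection(jags_model_string(two)), data = dat, inits = inits,
    n.chains = chains, n.adapt = adapt, quiet = quiet)
  update_progress <- if (quiet) "none" else "text"
  stats::update(model, n.iter = warmup, progress.bar = update_progress)
  monitors <- c("r", "q", "sigma2", "tau2", "P")
  samp <- rjags::coda.samples(model, variable.names = monitors,
                              n.iter = draws * thin, thin = thin,
                              progress.bar = update_progress)

  summ <- summarize_chains(samp)
  summ$scalar <- !grepl("^P\\[", summ$param)
  fit <- structure(
    list(scenario = spec$scenario_id,
         change_year_used = spec$change_year_used,
         K_assumed = K,
         summary = summ,
         sampler = list(chains = chains, draws = draws, warmup = warmup,
                        adapt = adapt, thin = thin, seed = seed)),
    class = "scenario_fit")
  fit$converged <- check_convergence(fit)
  fit
}

# posterior summaries + diagnostics from an mcmc.list
summarize_chains <- function(samp) {
  mats <- lapply(samp, as.matrix)
  all <- do.call(rbind, mats)
  ess <- coda::effectiveSize(samp)
  rhat <- vapply(colnames(all), function(p) {
    split_rhat(sapply(mats, function(m) m[, p]))
  }, numeric(1L))
  data.frame(
    param = colnames(all),
    mean = colMeans(all),
    sd = apply(all, 2L, stats::sd),
    lower = apply(all, 2L, stats::quantile, probs = 0.025),
    upper = apply(all, 2L, stats::quantile, probs = 0.975),
    ess = as.numeric(ess[colnames(all)]),
    rhat = rhat,
    row.names = NULL
  )
}

#' Split-chain potential scale reduction factor
#'
#' Computes the rank-free split-chain R-hat: each chain is halved, and the
#' usual between/within variance ratio is formed over the resulting
#' half-chains. Values near 1 indicate the chains sample the same
#' distribution; values above ~1.05 indicate non-convergence.
#'
#' @param draws A matrix with one column per chain (iterations in rows), or
#'   a single numeric vector (treated as one chain).
#' @return The scale-reduction statistic (a single number).
#' @export
#' @examples
#' set.seed(1)
#' split_rhat(cbind(rnorm(500), rnorm(500)))         # ~ 1
#' split_rhat(cbind(rnorm(500), rnorm(500, 10)))     # >> 1
split_rhat <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  half <- floor(n / 2)
  splits <- do.call(cbind, lapply(seq_len(ncol(draws)), function(j) {
    cbind(draws[seq_len(half), j], draws[(n - half + 1L):n, j])
  }))
  m <- ncol(splits)
  nn <- nrow(splits)
  means <- colMeans(splits)
  vars <- apply(splits, 2L, stats::var)
  W <- mean(vars)
  B <- nn * stats::var(means)
  if (W == 0) return(if (B == 0) 1 else Inf)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

#' Decide whether an MCMC fit converged
#'
#' A fit is declared converged when every structural (non-latent) monitored
#' parameter has split-chain scale reduction below `rhat_max` and effective
#' sample size of at least `ess_min`. Latent-state summaries are not part
#' of the criterion.
#'
#' @param fit A `scenario_fit` (or any list with a `summary` data frame
#'   holding `rhat`, `ess` and logical `scalar` columns).
#' @param rhat_max Scale-reduction threshold.
#' @param ess_min Minimum effective sample size.
#' @return Logical flag.
#' @export
check_convergence <- function(fit, rhat_max = 1.05, ess_min = 100) {
  s <- fit$summary
  s <- s[s$scalar, , drop = FALSE]
  all(is.finite(s$rhat)) && all(s$rhat < rhat_max) && all(s$ess >= ess_min)
}

#' @export
print.scenario_fit <- function(x, ...) {
  cat(sprintf("Scenario %d surplus-production fit (change year used: %s)\n",
              x$scenario,
              if (is.null(x$change_year_used)) "none" else x$change_year_used))
  cat(sprintf("  %d chains x %d draws; converged: %s\n",
              x$sampler$chains, x$sampler$draws, x$converged))
  print(x$summary[x$summary$scalar,
                  c("param", "mean", "sd", "lower", "upper", "ess", "rhat")],
        row.names = FALSE, digits = 4)
  invisible(x)
}
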