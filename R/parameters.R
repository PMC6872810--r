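#' Construct the generative parameters of one simulated population
#'
#' Bundles the true parameters of a Schaefer surplus-production world with a
#' single structural change: growth rate and catchability switch from
#' (`r1`, `q1`) to (`r2`, `q2`) at `change_year` of the analyzed series.
#'
#' @param r1 Intrinsic growth rate per year before the change. Must satisfy
#'   `r1 >= r2 > 0`.
#' @param r2 Growth rate per year after the change.
#' @param q1 Catchability coefficient (per metre of net) before the change.
#' @param q2 Catchability coefficient after the change.
#' @param K Carrying capacity, in biomass units.
#' @param B0 Initial biomass at the start of the stabilization segment;
#'   `0 < B0 <= K`.
#' @param change_year Integer year index (0-based, within the analyzed
#'   series) at which the regime switches; the first year generated under
#'   (`r2`, `q2`) is `change_year` itself.
#' @param n_years Length of the analyzed series in years.
#' @param stabilization_years Length of the burn-in segment simulated before
#'   the analyzed series so the population starts near its harvested
#'   equilibrium.
#' @param effort_mean Mean of the Poisson distribution from which yearly
#'   effort (metres of net) is drawn.
#' @param catch_noise_var Variance of the Gaussian log-scale multiplicative
#'   error on catch. The default 0.01 corresponds to a log-scale standard
#'   deviation of 0.1 (roughly 10% noise on yearly catch).
#'
#' @return An object of class `population_parameters` (a named list).
#' @seealso [sample_parameters()], [simulate_series()]
#' @export
#' @examples
#' population_parameters(r1 = 0.8, r2 = 0.3, q1 = 1.5e-5, q2 = 2.5e-5)
population_parameters <- function(r1, r2, q1, q2,
                                  K = 2e6, B0 = 1.5e6,
                                  change_year = 32L, n_years = 64L,
                                  stabilization_years = 32L,
                                  effort_mean = 1e4,
                                  catch_noise_var = 0.01) {
  stopifnot(is.numeric(r1), is.numeric(r2), is.numeric(q1), is.numeric(q2))
  if (!(r1 >= r2 && r2 > 0)) stop("require r1 >= r2 > 0")
  if (!(q1 > 0 && q2 > 0)) stop("require q1 > 0 and q2 > 0")
  if (!(K > 0)) stop("require K > 0")
  if (!(B0 > 0 && B0 <= K)) stop("require 0 < B0 <= K")
  change_year <- as.integer(change_year)
  n_years <- as.integer(n_years)
  if (!(change_year > 0 && change_year < n_years))
    stop("change_year must lie strictly inside the analyzed series")
  if (!(effort_mean > 0)) stop("require effort_mean > 0")
  if (catch_noise_var < 0) stop("require catch_noise_var >= 0")
  structure(
    list(r1 = r1, r2 = r2, q1 = q1, q2 = q2, K = K, B0 = B0,
         change_year = change_year, n_years = n_years,
         stabilization_years = as.integer(stabilization_years),
         effort_mean = effort_mean, catch_noise_var = catch_noise_var),
    class = "population_parameters"
  )
}

#' @export
print.population_parameters <- function(x, ...) {
  cat("Surplus-production parameters with a regime change at year",
      x$change_year, "of", x$n_years, "\n")
  cat(sprintf("  period 1: r1 = %.2f, q1 = %.2g\n", x$r1, x$q1))
  cat(sprintf("  period 2: r2 = %.2f, q2 = %.2g   (dr = %.2f, dq = %.2g)\n",
              x$r2, x$q2, x$r1 - x$r2, x$q1 - x$q2))
  cat(sprintf("  K = %s, B0 = %s, effort ~ Poisson(%s), log-catch var = %.3g\n",
              format(x$K, big.mark = ","), format(x$B0, big.mark = ","),
              format(x$effort_mean, big.mark = ","), x$catch_noise_var))
  invisible(x)
}

# Finite design sets from which one simulated world is drawn.
r1_set <- function() seq(0.55, 0.90, by = 0.05)
r2_set <- function() seq(0.20, 0.55, by = 0.05)
q1_set <- function() c(1.0, 1.5, 2.0, 2.5) * 1e-5
q2_set <- function() c(2.0, 2.5, 3.0) * 1e-5

#' Draw the generative parameters of one simulated world
#'
#' Samples each of `r1`, `r2`, `q1`, `q2` uniformly and independently from
#' its finite design set: `r1` from \{0.55, 0.60, ..., 0.90\}, `r2` from
#' \{0.20, 0.25, ..., 0.55\}, `q1` from \{1.0, 1.5, 2.0, 2.5\} x 1e-5 and
#' `q2` from \{2.0, 2.5, 3.0\} x 1e-5. The sets guarantee `r1 >= r2`, so a
#' growth-rate decline of `dr = r1 - r2` between 0 and 0.70 and a
#' catchability change `dq = q1 - q2` between -2.0e-5 and 0.5e-5. All other
#' fields take the study defaults (K = 2,000,000; B0 = 1,500,000; effort
#' mean 10,000; change at year 32 of 64; 32 stabilization years).
#'
#' Draws come from the R session RNG; call `set.seed()` first for
#' reproducibility.
#'
#' @param sets Optional named list overriding any of the design sets
#'   (`r1`, `r2`, `q1`, `q2`).
#' @param ... Passed on to [population_parameters()] to override the
#'   non-sampled fields.
#' @return A `population_parameters` object.
#' @export
#' @examples
#' set.seed(1)
#' sample_parameters()
sample_parameters <- function(sets = list(), ...) {
  pool <- list(r1 = r1_set(), r2 = r2_set(), q1 = q1_set(), q2 = q2_set())
  unknown <- setdiff(names(sets), names(pool))
  if (length(unknown))
    stop("unknown parameter set(s): ", paste(unknown, collapse = ", "))
  pool[names(sets)] <- sets
  if (min(pool$r1) < max(pool$r2))
    stop("design sets must guarantee r1 >= r2: min(r1 set) < max(r2 set)")
  draw <- function(s) s[sample.int(length(s), 1L)]
  population_parameters(r1 = draw(pool$r1), r2 = draw(pool$r2),
                        q1 = draw(pool$q1), q2 = draw(pool$q2), ...)
}
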