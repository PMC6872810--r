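# residual sum of squares of the pure-hinge (continuous piecewise-linear)
# OLS fit at fixed breakpoints p
hinge_rss <- function(year, cpue, p) {
  X <- cbind(1, year, pmax(year - p[1L], 0), pmax(year - p[2L], 0))
  sum(stats::.lm.fit(X, cpue)$residuals^2)
}

# coarse scan of the segmented RSS over integer breakpoint pairs; returns
# the best pair as a starting value for the iteration
grid_scan <- function(year, cpue, lo, hi) {
  ps <- seq(ceiling(lo) + 0.5, floor(hi) - 0.5, by = 1)
  best <- c(ps[1L], ps[2L])
  best_rss <- Inf
  for (i in seq_len(length(ps) - 2L)) {
    for (j in (i + 2L):length(ps)) {
      r <- hinge_rss(year, cpue, c(ps[i], ps[j]))
      if (r < best_rss) {
        best_rss <- r
        best <- c(ps[i], ps[j])
      }
    }
  }
  best
}

# One run of the iterative-linearization (Muggeo-type) breakpoint update:
# OLS of y on [1, t, (t - psi_k)_+, -I(t > psi_k)], then
# psi_k <- psi_k + gamma_k / beta_k. Steps that increase the segmented RSS
# are halved a few times but ultimately accepted (the update is not a
# descent direction in general); the best breakpoints visited are tracked.
muggeo_iterate <- function(year, cpue, psi, lo, hi, max_iter, tol) {
  rss_cur <- hinge_rss(year, cpue, psi)
  best_psi <- psi
  best_rss <- rss_cur
  converged <- FALSE
  n_iter <- 0L
  stagnant <- 0L
  for (it in seq_len(max_iter)) {
    n_iter <- it
    U <- cbind(pmax(year - psi[1L], 0), pmax(year - psi[2L], 0))
    V <- cbind(-(year > psi[1L]), -(year > psi[2L]))
    b <- stats::lm.fit(cbind(1, year, U, V), cpue)$coefficients
    bu <- b[3:4]
    gv <- b[5:6]
    if (anyNA(b)) {
      # singular linearized design: the breakpoints sit so close together
      # that hinge and step terms are collinear; the incumbent stands
      converged <- best_psi[1L] > lo && best_psi[2L] < hi
      break
    }
    if (any(abs(bu) < .Machine$double.eps)) break  # no slope change: flat data
    if (max(abs(gv)) < .Machine$double.eps) {      # gap closed
      converged <- TRUE
      break
    }
    delta <- gv / bu
    cand <- NULL
    h <- 1
    for (k in 1:6) {
      trial <- sort(pmin(pmax(psi + h * delta, lo), hi))
      if (trial[2L] - trial[1L] >= 2) {
        cand <- trial
        cand_rss <- hinge_rss(year, cpue, trial)
        if (cand_rss <= rss_cur) break
      }
      h <- h / 2
    }
    if (is.null(cand)) {
      # every admissible move collides the breakpoints: the incumbent is as
      # good as this run will get; treat an interior incumbent as settled
      converged <- best_psi[1L] > lo && best_psi[2L] < hi
      break
    }
    shift <- max(abs(cand - psi))
    psi <- cand
    rss_cur <- cand_rss
    if (rss_cur < best_rss * (1 - 1e-8)) stagnant <- 0L else stagnant <- stagnant + 1L
    if (rss_cur < best_rss) {
      best_rss <- rss_cur
      best_psi <- psi
    }
    # settled: either the breakpoints themselves stabilize, or the
    # objective has stopped improving while the update dithers around the
    # optimum (deviance-based convergence)
    if (shift < tol || stagnant >= 3L) {
      converged <- TRUE
      break
    }
  }
  # an update still dithering at max_iter, or pinned at the range
  # boundary, is a failed fit for this start
  if (converged && (best_psi[1L] <= lo || best_psi[2L] >= hi))
    converged <- FALSE
  list(psi = best_psi, rss = best_rss, converged = converged,
       n_iter = n_iter)
}

#' Two-breakpoint segmented regression by iterative linearization
#'
#' Fits the continuous piecewise-linear model
#' `y = b0 + b1 * t + d1 * (t - psi1)_+ + d2 * (t - psi2)_+ + e`
#' by the classical iterative-linearization scheme: at each iteration an
#' ordinary least-squares fit of `y` on the intercept, `t`, the hinge terms
#' `(t - psi_k)_+` and the negative step indicators `-I(t > psi_k)` is
#' computed, and each breakpoint is updated by the ratio of its step
#' coefficient to its hinge coefficient. Iteration stops when the largest
#' breakpoint move falls below `tol` or after `max_iter` iterations.
#'
#' Because the segmented RSS surface is non-smooth and multimodal under
#' noise, the core iteration is wrapped in bootstrap restarting: the
#' iteration is re-run on nonparametric bootstrap resamples of the data
#' starting from the incumbent breakpoints, each restart's solution is
#' polished on the original data, and the lowest-RSS solution wins. With
#' `n_boot = 0` the plain iteration is used alone. Bootstrap resampling
#' draws from the R session RNG.
#'
#' Breakpoints are kept sorted, constrained to lie at least two year units
#' inside the observed range, and kept at least two years apart (so every
#' segment retains points for identification). Convergence is declared when
#' the breakpoints stabilize or the objective stagnates while the update
#' dithers; a fit is flagged non-converged when the response carries no
#' breakpoint structure (rank-deficient or numerically linear data), when
#' the winning breakpoints are pinned at the admissible boundary, or when
#' the update never settles.
#'
#' @param year Numeric vector of time points (need not start at zero).
#' @param cpue Numeric response (catch per unit effort).
#' @param psi_init Length-2 vector of starting breakpoints, strictly inside
#'   the observed year range.
#' @param max_iter Maximum number of linearization iterations per run.
#' @param tol Convergence tolerance on the breakpoint update, in year units.
#' @param n_boot Number of bootstrap restarts.
#' @param grid_start If `TRUE`, a coarse scan of the RSS over integer
#'   breakpoint pairs seeds one extra run of the iteration, guarding
#'   against sharp optima (e.g. a jump in the level of the series) that
#'   gradient-like updates overshoot.
#' @param extra_starts Optional list of additional starting pairs (used by
#'   [estimate_joinpoint()] to share one grid scan across the five
#'   initializations).
#' @return A list of class `segmented_fit` with elements `psi` (sorted
#'   breakpoints), `coef` (named vector: intercept, slope, and the two
#'   hinge slope changes of the final pure-hinge refit), `rss`, `rss_line`
#'   (RSS of the one-line fit), `converged`, and `n_iter` (iterations used
#'   by the winning run).
#' @seealso [estimate_joinpoint()] for the multi-start averaging wrapper.
#' @export
#' @examples
#' t <- 0:63
#' y <- 10 - 3 * pmax(t - 20, 0) + 3 * pmax(t - 44, 0)
#' fit_segmented(t, y, c(16, 48))$psi
fit_segmented <- function(year, cpue, psi_init, max_iter = 50L, tol = 1e-4,
                          n_boot = 10L, grid_start = TRUE,
                          extra_starts = list()) {
  year <- as.numeric(year)
  cpue <- as.numeric(cpue)
  if (length(year) != length(cpue)) stop("year and cpue lengths differ")
  if (anyNA(year) || anyNA(cpue)) stop("missing values are not allowed")
  if (length(year) < 8L) stop("need at least 8 observations")
  if (diff(range(year)) == 0) stop("degenerate design: constant year vector")
  lo <- min(year) + 2
  hi <- max(year) - 2
  psi <- sort(as.numeric(psi_init))
  if (length(psi) != 2L || psi[1L] <= min(year) || psi[2L] >= max(year))
    stop("psi_init must be two values strictly inside the year range")

  rss_line <- sum(stats::lm.fit(cbind(1, year), cpue)$residuals^2)

  # a response that is linear in year to within floating-point noise has no
  # breakpoint structure to estimate: flag straight away rather than letting
  # the iteration settle on numerical dust
  if (rss_line <= length(year) * (1e-7 * (mean(abs(cpue)) + 1e-300))^2) {
    cf <- c(intercept = NA_real_, slope = NA_real_,
            dslope1 = NA_real_, dslope2 = NA_real_)
    return(structure(
      list(psi = psi, coef = cf, rss = rss_line, rss_line = rss_line,
           converged = FALSE, n_iter = 0L),
      class = "segmented_fit"))
  }

  best <- muggeo_iterate(year, cpue, psi, lo, hi, max_iter, tol)
  n <- length(year)
  starts <- extra_starts
  if (grid_start && best$rss > n * .Machine$double.eps)
    starts <- c(starts, list(grid_scan(year, cpue, lo, hi)))
  for (st in starts) {
    run <- muggeo_iterate(year, cpue, sort(st), lo, hi, max_iter, tol)
    if (run$rss < best$rss) best <- run
  }
  if (n_boot > 0L && best$rss > n * .Machine$double.eps) {
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      if (diff(range(year[idx])) < 4) next
      boot <- muggeo_iterate(year[idx], cpue[idx], best$psi,
                             min(year[idx]) + 2, max(year[idx]) - 2,
                             max_iter = 10L, tol = tol)
      polish <- muggeo_iterate(year, cpue, boot$psi, lo, hi, max_iter, tol)
      if (polish$rss < best$rss) best <- polish
    }
  }

  # final pure-hinge refit at the winning breakpoints
  psi <- best$psi
  Xf <- cbind(1, year, pmax(year - psi[1L], 0), pmax(year - psi[2L], 0))
  ff <- stats::lm.fit(Xf, cpue)
  cf <- ff$coefficients
  names(cf) <- c("intercept", "slope", "dslope1", "dslope2")
  converged <- best$converged && !anyNA(cf)
  structure(
    list(psi = unname(psi), coef = cf,
         rss = sum(ff$residuals^2), rss_line = rss_line,
         converged = converged, n_iter = best$n_iter),
    class = "segmented_fit"
  )
}

#' Default multi-start breakpoint initializations
#'
#' The five symmetric starting pairs used by the change-year estimator,
#' stated for a 64-year horizon and scaled proportionally for any other:
#' (16, 48), (18, 46), (20, 44), (22, 42), (24, 40).
#'
#' @param n_years Series horizon in years.
#' @return A list of five numeric length-2 vectors.
#' @export
joinpoint_inits <- function(n_years = 64L) {
  base <- list(c(16, 48), c(18, 46), c(20, 44), c(22, 42), c(24, 40))
  lapply(base, function(p) p * n_years / 64)
}

#' Estimate the change year of a CPUE series by multi-start joinpoint fits
#'
#' Runs [fit_segmented()] on CPUE against year from each of five
#' initializations (see [joinpoint_inits()]). Fits that do not converge are
#' dropped; across the survivors, the smaller breakpoints are averaged to
#' give `t1_star` (the estimated change year, continuous) and the larger to
#' give `t2_star` (the estimated end of the transient). The integer change
#' year `t_star` is `t1_star` rounded to the nearest integer (halves away
#' from zero), and the transition period is `|t1_star - t2_star|`.
#'
#' @param series An `spm_series` data frame from [simulate_series()], or any
#'   data frame with `year` and `cpue` columns (rows with missing CPUE are
#'   dropped).
#' @param inits List of starting pairs; defaults to [joinpoint_inits()] at
#'   the observed horizon.
#' @param max_iter,tol Passed to [fit_segmented()].
#' @return A list of class `joinpoint_estimate` with elements `t1_star`,
#'   `t2_star`, `t_star`, `transition`, `n_converged`, and `per_init` (the
#'   five `segmented_fit` objects).
#' @export
#' @examples
#' set.seed(11)
#' s <- simulate_series(population_parameters(0.85, 0.3, 1.5e-5, 2.5e-5))
#' estimate_joinpoint(s)[c("t1_star", "t2_star", "t_star", "transition")]
estimate_joinpoint <- function(series, inits = NULL, max_iter = 50L,
                               tol = 1e-4, n_boot = 5L) {
  if (!all(c("year", "cpue") %in% names(series)))
    stop("series must have 'year' and 'cpue' columns")
  keep <- !is.na(series$cpue)
  year <- series$year[keep]
  cpue <- series$cpue[keep]
  if (is.null(inits)) inits <- joinpoint_inits(length(year))
  # one coarse grid scan shared by all five starts
  gstart <- list(grid_scan(year, cpue, min(year) + 2, max(year) - 2))
  # each start gets an RNG stream derived from its own value, so the
  # result does not depend on the order the starts are tried in
  base_seed <- sample.int(2147483646L, 1L)
  fits <- lapply(inits, function(p) {
    set.seed((base_seed + round(1000 * p[1L])) %% 2147483647)
    tryCatch(fit_segmented(year, cpue, p, max_iter = max_iter, tol = tol,
                           n_boot = n_boot, grid_start = FALSE,
                           extra_starts = gstart),
             error = function(e) list(converged = FALSE, error = conditionMessage(e)))
  })
  ok <- vapply(fits, function(f) isTRUE(f$converged), logical(1L))
  if (!any(ok)) {
    stop(structure(
      class = c("joinpoint_no_convergence", "error", "condition"),
      list(message = "no joinpoint: none of the segmented initializations converged",
           call = sys.call(-1L))))
  }
  t1 <- mean(vapply(fits[ok], function(f) f$psi[1L], numeric(1L)))
  t2 <- mean(vapply(fits[ok], function(f) f$psi[2L], numeric(1L)))
  structure(
    list(t1_star = t1, t2_star = t2,
         t_star = round_half_away(t1),
         transition = abs(t2 - t1),
         n_converged = sum(ok), per_init = fits),
    class = "joinpoint_estimate"
  )
}

# round to nearest integer, halves away from zero (round() rounds halves to even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' @export
print.joinpoint_estimate <- function(x, ...) {
  cat(sprintf(
    "Joinpoint estimate: t1* = %.3f, t2* = %.3f, t* = %d, transition = %.3f yr (%d/%d inits converged)\n",
    x$t1_star, x$t2_star, as.integer(x$t_star), x$transition,
    x$n_converged, length(x$per_init)))
  invisible(x)
}
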