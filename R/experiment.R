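#' Relative bias of an estimate
#'
#' `(estimate - truth) / truth`. Vectorized; `percent = TRUE` gives the
#' table-facing scale.
#'
#' @param estimate Numeric estimate(s).
#' @param truth Nonzero numeric truth(s).
#' @param percent Multiply by 100.
#' @return Numeric vector of relative biases.
#' @export
#' @examples
#' relative_bias(0.6, 0.5)     # 0.2
#' relative_bias(33, 32)       # 0.03125
relative_bias <- function(estimate, truth, percent = FALSE) {
  if (any(truth == 0)) stop("relative bias is undefined for zero truth")
  rb <- (estimate - truth) / truth
  if (percent) 100 * rb else rb
}

# bin labels match the half-open boundaries of the study's figures/tables
dr_bin_labels <- c("[0.00,0.20]", "(0.20,0.45]", "(0.45,0.70]")
dq_bin_labels <- c("<=-1.5e-05", "(-1.5e-05,-5e-06]", ">-5e-06")

dr_bin <- function(dr) {
  cut(dr, breaks = c(0, 0.20, 0.45, 0.70), labels = dr_bin_labels,
      include.lowest = TRUE, right = TRUE)
}

dq_bin <- function(dq) {
  cut(dq, breaks = c(-Inf, -1.5e-5, -5e-6, Inf), labels = dq_bin_labels,
      right = TRUE)
}

#' Run the full simulation study
#'
#' Repeats, until `n_sims` simulations have been *accepted*: draw a
#' parameter set ([sample_parameters()]), simulate a series
#' ([simulate_series()]), estimate the change year
#' ([estimate_joinpoint()]), and fit each requested scenario
#' ([fit_scenario()]). A simulation is rejected — and fresh parameters
#' drawn — if the joinpoint estimation finds no breakpoint or any requested
#' MCMC fit fails its convergence check. With `scenarios = integer(0)` only
#' the (fast, least-squares) joinpoint stage runs.
#'
#' The whole study is reproducible from `seed`: per-attempt seeds are
#' pre-derived from the master seed, so the accepted records do not depend
#' on how rejections interleave.
#'
#' @param n_sims Number of accepted simulations required.
#' @param seed Master seed.
#' @param scenarios Subset of `c(1, 2, 3)`; empty for joinpoint-only runs.
#' @param mcmc Named list of MCMC settings passed to [fit_scenario()]
#'   (`chains`, `draws`, `warmup`, `adapt`, `thin`), plus the acceptance
#'   thresholds the study applies when deciding whether a fit converged
#'   (`rhat_max`, default 1.05; `ess_min`, default 100). Scaled-down
#'   studies may relax the thresholds; each fit's own `converged` flag
#'   always reflects the strict defaults.
#' @param sets Optional design-set overrides, as in [sample_parameters()].
#' @param stochastic Passed to [simulate_series()]; `FALSE` gives the
#'   deterministic model skeleton (mainly for degenerate-input checks).
#' @param max_reject_factor The study aborts if more than
#'   `max_reject_factor * n_sims` attempts are needed (guards against a
#'   misconfiguration that rejects everything).
#' @param out_dir Optional directory; if given, `records.csv`,
#'   `summary.json` and a `run_manifest.json` (seed, settings, package
#'   version) are written there.
#' @param progress Print a line every 100 accepted simulations.
#' @param ... Further arguments to [simulate_series()] or
#'   [sample_parameters()] overrides via `sets`.
#' @return A list of class `study_result`: `records` (data frame, one row
#'   per accepted simulation), `summary` (see [summarize_tables()]),
#'   `n_accepted`, `n_rejected`.
#' @export
#' @examples
#' \donttest{
#' st <- run_study(n_sims = 50, seed = 42)   # joinpoint stage only
#' st$summary$t1_mean
#' }
run_study <- function(n_sims, seed = 1L, scenarios = integer(0),
                      mcmc = list(), sets = list(), stochastic = TRUE,
                      max_reject_factor = 20, out_dir = NULL,
                      progress = FALSE, ...) {
  stopifnot(n_sims >= 1)
  scenarios <- sort(unique(as.integer(scenarios)))
  if (length(scenarios) && !all(scenarios %in% 1:3))
    stop("scenarios must be a subset of 1:3")
  mcmc_def <- list(chains = 2L, draws = 1000L, warmup = 500L,
                   adapt = 500L, thin = 1L, rhat_max = 1.05, ess_min = 100)
  unknown <- setdiff(names(mcmc), names(mcmc_def))
  if (length(unknown))
    stop("unknown mcmc setting(s): ", paste(unknown, collapse = ", "))
  mcmc_def[names(mcmc)] <- mcmc
  max_attempts <- ceiling(max_reject_factor * n_sims)
  set.seed(as.integer(seed))
  attempt_seeds <- sample.int(.Machine$integer.max - 1L, max_attempts)

  records <- vector("list", n_sims)
  n_acc <- 0L
  n_rej <- 0L
  attempt <- 0L
  while (n_acc < n_sims) {
    attempt <- attempt + 1L
    if (attempt > max_attempts)
      stop("rejection ceiling exceeded: ", n_rej, " rejections for ",
           n_acc, " accepted simulations")
    sim_seed <- attempt_seeds[attempt]
    set.seed(sim_seed)
    params <- sample_parameters(sets = sets, ...)
    series <- simulate_series(params, stochastic = stochastic)
    jp <- tryCatch(estimate_joinpoint(series),
                   joinpoint_no_convergence = function(e) NULL)
    if (is.null(jp)) {
      n_rej <- n_rej + 1L
      next
    }
    rec <- data.frame(
      sim_id = NA_integer_, seed = sim_seed,
      r1 = params$r1, r2 = params$r2, q1 = params$q1, q2 = params$q2,
      delta_r = params$r1 - params$r2, delta_q = params$q1 - params$q2,
      t1_star = jp$t1_star, t2_star = jp$t2_star,
      t_star = jp$t_star, transition = jp$transition,
      n_init_converged = jp$n_converged
    )
    rec$dr_bin <- as.character(dr_bin(rec$delta_r))
    rec$dq_bin <- as.character(dq_bin(rec$delta_q))

    rejected <- FALSE
    for (sc in scenarios) {
      spec <- switch(as.character(sc),
        "1" = scenario_spec(1L, K_assumed = params$K),
        "2" = scenario_spec(2L, change_year = jp$t_star,
                            K_assumed = params$K),
        "3" = scenario_spec(3L, change_year = params$change_year,
                            K_assumed = params$K))
      fit <- tryCatch(
        fit_scenario(series, spec, chains = mcmc_def$chains,
                     draws = mcmc_def$draws, warmup = mcmc_def$warmup,
                     adapt = mcmc_def$adapt, thin = mcmc_def$thin,
                     seed = sim_seed %% 1000000L + sc),
        error = function(e) NULL)
      if (is.null(fit) ||
          !check_convergence(fit, rhat_max = mcmc_def$rhat_max,
                             ess_min = mcmc_def$ess_min)) {
        rejected <- TRUE
        break
      }
      s <- fit$summary
      pm <- function(p) {
        v <- s$mean[s$param == p]
        if (!length(v)) v <- s$mean[s$param == sub("\\[1\\]$", "", p)]
        v
      }
      pre <- paste0("s", sc, "_")
      if (sc == 1L) {
        rec[[paste0(pre, "r_hat")]] <- pm("r[1]")
        rec[[paste0(pre, "q_hat")]] <- pm("q[1]")
        rec[[paste0(pre, "r1_bias")]] <- relative_bias(pm("r[1]"), params$r1)
        rec[[paste0(pre, "q1_bias")]] <- relative_bias(pm("q[1]"), params$q1)
      } else {
        rec[[paste0(pre, "r1_hat")]] <- pm("r[1]")
        rec[[paste0(pre, "r2_hat")]] <- pm("r[2]")
        rec[[paste0(pre, "q1_hat")]] <- pm("q[1]")
        rec[[paste0(pre, "q2_hat")]] <- pm("q[2]")
        rec[[paste0(pre, "r1_bias")]] <- relative_bias(pm("r[1]"), params$r1)
        rec[[paste0(pre, "r2_bias")]] <- relative_bias(pm("r[2]"), params$r2)
        rec[[paste0(pre, "q1_bias")]] <- relative_bias(pm("q[1]"), params$q1)
        rec[[paste0(pre, "q2_bias")]] <- relative_bias(pm("q[2]"), params$q2)
      }
    }
    if (rejected) {
      n_rej <- n_rej + 1L
      next
    }
    n_acc <- n_acc + 1L
    rec$sim_id <- n_acc
    records[[n_acc]] <- rec
    if (progress && n_acc %% 100L == 0L)
      message("accepted ", n_acc, "/", n_sims, " (", n_rej, " rejected)")
  }
  records <- do.call(rbind, records)
  summary <- summarize_tables(records, n_rejected = n_rej)
  res <- structure(list(records = records, summary = summary,
                        n_accepted = n_acc, n_rejected = n_rej,
                        seed = as.integer(seed), scenarios = scenarios,
                        mcmc = mcmc_def),
                   class = "study_result")
  if (!is.null(out_dir)) write_study(res, out_dir)
  res
}

#' Summarize a study into headline statistics and bias tables
#'
#' Computes, across accepted simulations: mean and variance of the two
#' averaged breakpoints `t1_star` and `t2_star`; a normal-theory 95%
#' confidence interval for the mean relative bias of `t1_star` against the
#' true change year; mean/min/max transition period; the variance ratio of
#' `t1_star` between small (`delta_r < 0.10`) and larger growth-rate
#' changes; and, when scenario fits are present, per-bin per-scenario mean
#' relative bias (in %) with its sample standard deviation for each of
#' `r1`, `r2`, `q1`, `q2` (growth-rate tables binned by `delta_r`,
#' catchability tables by `delta_q`). Empty bins are reported as `NA`,
#' never zero.
#'
#' @param records The records data frame from [run_study()].
#' @param true_change_year True change year used for the joinpoint bias.
#' @param n_rejected Optional rejection count to carry into the summary.
#' @return A list of class `study_summary`.
#' @export
summarize_tables <- function(records, true_change_year = 32,
                             n_rejected = NA_integer_) {
  stopifnot(nrow(records) >= 1L)
  rb_t1 <- relative_bias(records$t1_star, true_change_year)
  n <- nrow(records)
  se <- stats::sd(rb_t1) / sqrt(n)
  small <- records$delta_r < 0.10
  var_ratio <- if (any(small) && any(!small) && sum(small) > 1 && sum(!small) > 1)
    stats::var(records$t1_star[small]) / stats::var(records$t1_star[!small])
  else NA_real_

  bias_table <- function(param, bin_col, labels) {
    cols <- grep(paste0("^s[123]_", param, "_bias$"), names(records),
                 value = TRUE)
    if (!length(cols)) return(NULL)
    tab <- expand.grid(bin = labels, scenario = 1:3,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    tab$mean_pct <- tab$sd_pct <- tab$n <- NA_real_
    for (i in seq_len(nrow(tab))) {
      col <- paste0("s", tab$scenario[i], "_", param, "_bias")
      if (!col %in% names(records)) next
      x <- records[[col]][records[[bin_col]] == tab$bin[i]]
      x <- x[!is.na(x)]
      tab$n[i] <- length(x)
      if (length(x)) {
        tab$mean_pct[i] <- 100 * mean(x)
        tab$sd_pct[i] <- if (length(x) > 1) 100 * stats::sd(x) else NA_real_
      }
    }
    tab
  }

  structure(list(
    n_accepted = n, n_rejected = n_rejected,
    t1_mean = mean(records$t1_star), t1_var = stats::var(records$t1_star),
    t2_mean = mean(records$t2_star), t2_var = stats::var(records$t2_star),
    t1_bias_mean = mean(rb_t1),
    t1_bias_ci = mean(rb_t1) + c(-1, 1) * 1.96 * se,
    transition_mean = mean(records$transition),
    transition_min = min(records$transition),
    transition_max = max(records$transition),
    t1_var_ratio_small_dr = var_ratio,
    table_r1 = bias_table("r1", "dr_bin", dr_bin_labels),
    table_r2 = bias_table("r2", "dr_bin", dr_bin_labels),
    table_q1 = bias_table("q1", "dq_bin", dq_bin_labels),
    table_q2 = bias_table("q2", "dq_bin", dq_bin_labels)
  ), class = "study_summary")
}

#' @export
print.study_summary <- function(x, ...) {
  cat("Simulation study summary\n")
  cat(sprintf("  accepted: %d   rejected: %s\n", x$n_accepted,
              ifelse(is.na(x$n_rejected), "?", x$n_rejected)))
  cat(sprintf("  t1*: mean %.2f, var %.2f   t2*: mean %.2f, var %.2f\n",
              x$t1_mean, x$t1_var, x$t2_mean, x$t2_var))
  cat(sprintf("  mean relative bias of t1*: %.4f (95%% CI %.4f, %.4f)\n",
              x$t1_bias_mean, x$t1_bias_ci[1], x$t1_bias_ci[2]))
  cat(sprintf("  transition period: mean %.2f (range %.2f-%.2f) years\n",
              x$transition_mean, x$transition_min, x$transition_max))
  if (is.finite(x$t1_var_ratio_small_dr))
    cat(sprintf("  var(t1*) ratio, dr < 0.10 vs dr >= 0.10: %.2f\n",
                x$t1_var_ratio_small_dr))
  for (nm in c("table_r1", "table_r2", "table_q1", "table_q2")) {
    if (!is.null(x[[nm]])) {
      cat("  mean relative bias (%), ", sub("table_", "", nm), ":\n", sep = "")
      print(x[[nm]], row.names = FALSE, digits = 4)
    }
  }
  invisible(x)
}

# write records + summary + manifest for a study run
write_study <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(res$records, file.path(out_dir, "records.csv"),
                   row.names = FALSE)
  s <- res$summary
  jsonlite::write_json(
    s[!vapply(s, is.data.frame, logical(1L))],
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  for (nm in c("table_r1", "table_r2", "table_q1", "table_q2"))
    if (!is.null(s[[nm]]))
      utils::write.csv(s[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                       row.names = FALSE)
  manifest <- list(
    package = "joinpointSPM",
    version = as.character(utils::packageVersion("joinpointSPM")),
    seed = res$seed, n_sims = res$n_accepted, scenarios = res$scenarios,
    mcmc = res$mcmc)
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
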