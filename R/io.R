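#' Default study configuration
#'
#' All tunables of the pipeline in one named list, with every default set
#' to the study's generative design: carrying capacity 2,000,000; initial
#' biomass 1,500,000; Poisson effort mean 10,000; log-scale catch noise
#' variance 0.01 (sd 0.1); a 32-year stabilization segment before 64 analyzed years
#' with the change at year 32; the four finite parameter design sets; the
#' five breakpoint initializations with tolerance 1e-4 and 50 iterations;
#' the MCMC settings and prior configuration of [fit_scenario()]; and the
#' delta-r / delta-q bin edges of the bias tables.
#'
#' @return A named list of class `study_config`.
#' @export
default_config <- function() {
  structure(list(
    seed = 1L,
    n_years = 64L,
    stabilization_years = 32L,
    change_year = 32L,
    K = 2e6,
    B0 = 1.5e6,
    effort_mean = 1e4,
    catch_noise_var = 0.01,
    r1_set = r1_set(),
    r2_set = r2_set(),
    q1_set = q1_set(),
    q2_set = q2_set(),
    joinpoint_inits = joinpoint_inits(64L),
    segmented_tol = 1e-4,
    segmented_max_iter = 50L,
    mcmc = list(chains = 2L, draws = 1000L, warmup = 500L, adapt = 500L,
                thin = 1L),
    prior = prior_config(),
    dr_bin_edges = c(0, 0.20, 0.45, 0.70),
    dq_bin_edges = c(-Inf, -1.5e-5, -5e-6, Inf),
    out_dir = NULL
  ), class = "study_config")
}

validate_config <- function(cfg) {
  if (min(cfg$r1_set) < max(cfg$r2_set))
    stop("invalid config key 'r2_set': violates r1 >= r2 against 'r1_set'")
  for (key in c("K", "B0", "effort_mean"))
    if (!(is.numeric(cfg[[key]]) && cfg[[key]] > 0))
      stop("invalid config key '", key, "': must be a positive number")
  if (cfg$B0 > cfg$K) stop("invalid config key 'B0': exceeds K")
  if (cfg$catch_noise_var < 0)
    stop("invalid config key 'catch_noise_var': negative")
  if (!(cfg$change_year > 0 && cfg$change_year < cfg$n_years))
    stop("invalid config key 'change_year': outside the analyzed series")
  if (any(vapply(cfg$q1_set, function(q) q <= 0, logical(1L))) ||
      any(vapply(cfg$q2_set, function(q) q <= 0, logical(1L))))
    stop("invalid config key 'q1_set'/'q2_set': catchabilities must be positive")
  invisible(cfg)
}

#' Load a study configuration from YAML
#'
#' Reads a YAML (or JSON; JSON is a YAML subset) file and overlays it on
#' [default_config()], so an empty file yields all defaults. Unknown keys
#' are rejected with their names; invariants (positive K, `B0 <= K`,
#' design sets compatible with `r1 >= r2`, change year inside the series)
#' are validated.
#'
#' @param path Path to the config file.
#' @return A validated `study_config` list.
#' @seealso [save_config()]
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  if (length(user)) {
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown))
      stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    for (nm in names(user)) {
      if (is.list(cfg[[nm]]) && !is.null(names(cfg[[nm]]))) {
        sub_unknown <- setdiff(names(user[[nm]]), names(cfg[[nm]]))
        if (length(sub_unknown))
          stop("unknown config key(s) under '", nm, "': ",
               paste(sub_unknown, collapse = ", "))
        cfg[[nm]][names(user[[nm]])] <- user[[nm]]
      } else {
        cfg[[nm]] <- user[[nm]]
      }
    }
  }
  # yaml flattens the list of init pairs to a list of 2-vectors already
  cfg$joinpoint_inits <- lapply(cfg$joinpoint_inits, as.numeric)
  class(cfg) <- "study_config"
  validate_config(cfg)
}

#' Save a study configuration as YAML
#'
#' @param cfg A `study_config` list.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  drop_null <- cfg[!vapply(cfg, is.null, logical(1L))]
  yaml::write_yaml(drop_null, path)
  invisible(path)
}

#' Read a yearly catch/effort series from CSV
#'
#' Expects a header with at least `year`, `effort`, `catch` (comma
#' separated, '.' decimal). A `biomass` column is optional — real data
#' never has one — and `cpue` is recomputed as `catch / effort` when
#' absent; years with zero effort get missing CPUE.
#'
#' @param path CSV file path.
#' @return An `spm_series` data frame.
#' @export
read_series_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("year", "effort", "catch")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("series CSV missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(d$cpue))
    d$cpue <- ifelse(d$effort > 0, d$catch / d$effort, NA_real_)
  if (is.null(d$biomass)) d$biomass <- NA_real_
  d <- d[, c("year", "biomass", "effort", "catch", "cpue")]
  class(d) <- c("spm_series", "data.frame")
  d
}

#' Write a yearly series to CSV
#'
#' @param series An `spm_series` or compatible data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(series, path) {
  utils::write.csv(
    as.data.frame(series)[, c("year", "biomass", "effort", "catch", "cpue")],
    path, row.names = FALSE)
  invisible(path)
}
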