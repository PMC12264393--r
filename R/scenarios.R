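# Experiment drivers: habitat-loss levels, back-up contrasts, replicate
# ensembles, rejection-rate grid sweeps and sensitivity analysis.

#' Describe a simulation scenario
#'
#' @param hlf_level Habitat-loss-and-fragmentation level as the retained
#'   fraction of baseline capacity: 1 (none), 0.75 (moderate), 0.5 (severe).
#'   Other values in (0, 1] are allowed for custom experiments.
#' @param backup Whether cuckoo back-up host switching is enabled.
#' @param years Simulation horizon in years.
#' @param n_replicates Number of independent replicate runs.
#' @param master_seed Master seed; each replicate derives its own stream so
#'   replicates are reproducible and order-independent.
#' @param overrides Named list of [set_param()] overrides applied to the
#'   configuration before running.
#' @return An object of class `bp_scenario`.
#' @export
scenario_spec <- function(hlf_level = 1, backup = TRUE, years = 300L,
                          n_replicates = 100L, master_seed = 1L,
                          overrides = list()) {
  if (hlf_level <= 0 || hlf_level > 1) .invalid_config("hlf_level must be in (0, 1]")
  years <- as.integer(years)
  if (years < 1L) .invalid_config("years must be >= 1")
  n_replicates <- as.integer(n_replicates)
  if (n_replicates < 1L) .invalid_config("n_replicates must be >= 1")
  structure(list(hlf_level = hlf_level, backup = isTRUE(backup), years = years,
                 n_replicates = n_replicates,
                 master_seed = as.integer(master_seed),
                 overrides = overrides),
            class = "bp_scenario")
}

#' Scale a configuration for habitat loss and fragmentation
#'
#' HLF is modelled as a proportional reduction of the host carrying capacity,
#' with the year-zero population sizes of both species scaled down by the same
#' factor. All other parameters are untouched.
#'
#' @param config A [bp_config()].
#' @param level Retained fraction of baseline capacity, in (0, 1].
#' @return The scaled configuration.
#' @examples
#' cfg <- make_fixture("A")
#' apply_hlf(cfg, 0.75)$host$capacity # 75% of baseline K
#' @export
apply_hlf <- function(config, level) {
  stopifnot(inherits(config, "bp_config"))
  if (level <= 0 || level > 1) .invalid_config("hlf level must be in (0, 1]")
  if (level == 1) return(config)
  config$host <- .rebuild_species(config$host,
                                  capacity = as.integer(round(config$host$capacity * level)),
                                  n_initial = as.integer(round(config$host$n_initial * level)))
  config$cuckoos <- lapply(config$cuckoos, function(p) {
    .rebuild_species(p, n_initial = as.integer(round(p$n_initial * level)))
  })
  config
}

# Per-replicate seeds derived from the master seed; independent of execution
# order and kept inside 32-bit integer range.
.replicate_seeds <- function(master_seed, n) {
  as.integer((as.double(master_seed) * 1009 + 7919 * seq_len(n)) %% 2147483647) + 1L
}

#' Run a replicate ensemble of one scenario
#'
#' Applies the scenario (HLF scaling, back-up flag, parameter overrides) to
#' the configuration, runs `n_replicates` independent simulations with split
#' seeds, and collects per-year relative-population and parasitism-ratio
#' series with median, mean and 5/25/75/95 percentile summaries, the
#' per-replicate survival periods and final-year RP values. Replicates halt
#' when the parasite goes extinct; their series are padded with zeros to the
#' horizon.
#'
#' @param config A [bp_config()].
#' @param scenario A [scenario_spec()].
#' @param keep_records Keep every replicate's full year-by-year record
#'   (needed by [write_results()] and [band_coverage()]).
#' @return An object of class `bp_ensemble`: matrices `rp` and `pr`
#'   (years+1 rows x replicates), `summary` (per-year data frame),
#'   `survival_periods`, `rp_final`, `seeds`, the applied `config` and
#'   `scenario`, and optionally `records`.
#' @export
run_ensemble <- function(config, scenario = scenario_spec(), keep_records = TRUE) {
  stopifnot(inherits(config, "bp_config"), inherits(scenario, "bp_scenario"))
  cfg <- apply_hlf(config, scenario$hlf_level)
  cfg$backup <- scenario$backup
  for (nm in names(scenario$overrides)) {
    cfg <- set_param(cfg, nm, scenario$overrides[[nm]])
  }
  years <- scenario$years
  R <- scenario$n_replicates
  seeds <- .replicate_seeds(scenario$master_seed, R)
  ny <- years + 1L
  rp <- matrix(NA_real_, ny, R, dimnames = list(0:years, NULL))
  pr <- matrix(NA_real_, ny, R, dimnames = list(0:years, NULL))
  surv <- numeric(R)
  records <- if (keep_records) vector("list", R)
  for (r in seq_len(R)) {
    sim <- run_simulation(cfg, years = years, seed = seeds[r], halt = "parasite")
    k <- nrow(sim)
    rp[seq_len(k), r] <- sim$rp
    pr[seq_len(k), r] <- sim$pr
    if (k < ny) { # parasite extinct before the horizon
      rp[(k + 1L):ny, r] <- 0
      pr[(k + 1L):ny, r] <- 0
    }
    counts <- c(sim$cuckoo_n, rep.int(0L, ny - k))
    surv[r] <- survival_period(counts, horizon = years)
    if (keep_records) records[[r]] <- sim
  }
  pr[1L, ] <- NA_real_ # year 0 has no breeding season
  q <- function(m, p) unname(apply(m, 1L, stats::quantile, probs = p,
                                   na.rm = TRUE, names = FALSE))
  summary <- data.frame(
    year = 0:years,
    rp_median = unname(apply(rp, 1L, stats::median)),
    rp_mean = unname(rowMeans(rp)),
    rp_q05 = q(rp, 0.05), rp_q25 = q(rp, 0.25),
    rp_q75 = q(rp, 0.75), rp_q95 = q(rp, 0.95),
    pr_median = unname(apply(pr, 1L, stats::median, na.rm = TRUE)),
    pr_mean = unname(rowMeans(pr, na.rm = TRUE)),
    pr_q05 = q(pr, 0.05), pr_q25 = q(pr, 0.25),
    pr_q75 = q(pr, 0.75), pr_q95 = q(pr, 0.95)
  )
  structure(list(rp = rp, pr = pr, summary = summary,
                 survival_periods = surv, rp_final = unname(rp[ny, ]),
                 seeds = seeds, config = cfg, scenario = scenario,
                 records = if (keep_records) records),
            class = "bp_ensemble")
}

#' @export
print.bp_ensemble <- function(x, ...) {
  sc <- x$scenario
  cat("<bp_ensemble>", sc$n_replicates, "replicates x", sc$years, "years",
      "| HLF", sc$hlf_level, "| backup", sc$backup, "\n")
  cat("  median final RP:", round(stats::median(x$rp_final), 1), "%",
      "| median survival:", stats::median(x$survival_periods), "years\n")
  invisible(x)
}

#' Convert a rejection rate to the corresponding mimicry probability
#'
#' The rejection rate (RR) on a channel is the host's detection capacity
#' minus the cuckoo's mimicry capacity, so the mimicry probability realizing
#' a target RR is `host_level - rr`.
#'
#' @param rr Rejection rate(s), in `[0, host_level]`.
#' @param host_level Host detection probability for the channel (default the
#'   standardized 0.40).
#' @return Mimicry probability (vectorized).
#' @examples
#' rr_to_mimicry(0.25) # 0.15, the population-A setting
#' @export
rr_to_mimicry <- function(rr, host_level = 0.40) {
  if (any(rr < 0) || any(rr > host_level)) {
    .invalid_config("rr must lie in [0, host_level]")
  }
  host_level - rr
}

#' Sweep a grid of colour and shape rejection rates
#'
#' For every (colour RR, shape RR) cell, sets the single cuckoo group's
#' mimicry probabilities to `host_level - rr` on each channel (all other
#' settings fixed) and runs an ensemble, recording the median survival period
#' and the median final-year RP.
#'
#' @param config Base configuration (single cuckoo group).
#' @param scenario A [scenario_spec()] applied to every cell.
#' @param color_rr_values,shape_rr_values Ascending RR grids in
#'   `[0, host_level]` (default 0 to 0.40 in 5% steps).
#' @param host_level Host detection level on both channels.
#' @return Data frame: `color_rr`, `shape_rr`, `median_survival`,
#'   `median_rp_final`.
#' @export
rr_grid_sweep <- function(config, scenario = scenario_spec(),
                          color_rr_values = seq(0, 0.40, by = 0.05),
                          shape_rr_values = seq(0, 0.40, by = 0.05),
                          host_level = 0.40) {
  stopifnot(inherits(config, "bp_config"))
  if (is.unsorted(color_rr_values) || is.unsorted(shape_rr_values)) {
    .invalid_config("RR grids must be ascending")
  }
  grid <- expand.grid(color_rr = color_rr_values, shape_rr = shape_rr_values,
                      KEEP.OUT.ATTRS = FALSE)
  grid$median_survival <- NA_real_
  grid$median_rp_final <- NA_real_
  for (i in seq_len(nrow(grid))) {
    cfg <- set_param(config, "cuckoo_mimic_color",
                     rr_to_mimicry(grid$color_rr[i], host_level))
    cfg <- set_param(cfg, "cuckoo_mimic_shape",
                     rr_to_mimicry(grid$shape_rr[i], host_level))
    ens <- run_ensemble(cfg, scenario, keep_records = FALSE)
    grid$median_survival[i] <- stats::median(ens$survival_periods)
    grid$median_rp_final[i] <- stats::median(ens$rp_final)
  }
  grid
}

#' One-at-a-time sensitivity sweep
#'
#' Runs one ensemble per tested value of a single parameter, everything else
#' fixed at the baseline, and records the median final-year RP and the median
#' final-year parasitism ratio.
#'
#' @param config Baseline configuration.
#' @param param One of `"cuckoo_fertility"`, `"host_fertility"`,
#'   `"cuckoo_lifespan_max"`, `"host_lifespan_max"`, `"host_rearing"`,
#'   `"ch_ratio"`.
#' @param values Non-empty vector of parameter values to test.
#' @param scenario A [scenario_spec()] applied to every value.
#' @return Data frame: `param`, `value`, `median_rp_final`, `median_pr_final`.
#' @export
sensitivity_sweep <- function(config, param, values,
                              scenario = scenario_spec()) {
  allowed <- c("cuckoo_fertility", "host_fertility", "cuckoo_lifespan_max",
               "host_lifespan_max", "host_rearing", "ch_ratio")
  if (!param %in% allowed) {
    .invalid_config(paste0("unknown sensitivity parameter: ", param))
  }
  if (!length(values)) .invalid_config("sensitivity values must be non-empty")
  out <- data.frame(param = param, value = as.numeric(values),
                    median_rp_final = NA_real_, median_pr_final = NA_real_)
  ny <- scenario$years + 1L
  for (i in seq_along(values)) {
    cfg <- set_param(config, param, values[i])
    ens <- run_ensemble(cfg, scenario, keep_records = FALSE)
    out$median_rp_final[i] <- stats::median(ens$rp_final)
    out$median_pr_final[i] <- stats::median(ens$pr[ny, ], na.rm = TRUE)
  }
  out
}
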