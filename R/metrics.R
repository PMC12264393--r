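# Summary statistics and validation comparisons. All metrics are pure
# functions of recorded series; none consume randomness.

.invalid_input <- function(msg) {
  stop(errorCondition(msg, class = c("bp_invalid_input", "error")))
}

#' Relative population (RP)
#'
#' The ratio of each year's population to the year-zero population, in
#' percent. 100 at year 0; 0 after extinction.
#'
#' @param counts Census counts (year 0 first, or any series).
#' @param n0 Year-zero population, `> 0`.
#' @return Numeric vector of RP values in percent.
#' @examples
#' relative_population(c(100, 60, 0), 100) # 100 60 0
#' @export
relative_population <- function(counts, n0) {
  if (length(n0) != 1L || is.na(n0) || n0 <= 0) {
    .invalid_input("relative_population: n0 must be a single positive count")
  }
  100 * counts / n0
}

#' Parasitism ratio (PR)
#'
#' Parasitized nests over total nests observed in a year. With zero nests the
#' ratio is undefined and reported as 0, flagged via the `"undefined"`
#' attribute.
#'
#' @param parasitized Number of parasitized nests (`<= total_nests`).
#' @param total_nests Total nests observed.
#' @return Proportion(s) in `[0, 1]`; attribute `undefined` marks zero-nest
#'   years.
#' @examples
#' parasitism_ratio(3, 20) # 0.15
#' @export
parasitism_ratio <- function(parasitized, total_nests) {
  if (any(total_nests < 0, na.rm = TRUE)) .invalid_input("parasitism_ratio: total_nests < 0")
  if (any(parasitized > total_nests, na.rm = TRUE)) {
    .invalid_input("parasitism_ratio: parasitized exceeds total_nests")
  }
  out <- ifelse(total_nests > 0, parasitized / total_nests, 0)
  undef <- total_nests == 0
  if (any(undef, na.rm = TRUE)) attr(out, "undefined") <- which(undef)
  out
}

#' Subtraction of relative population (SRP)
#'
#' The survival value of back-up host switching: year-300 RP with back-up
#' behaviour enabled minus the RP without it, in percentage points.
#'
#' @param rp_with_backup,rp_without_backup Final-year RP values (percent).
#' @return Difference in percentage points (may be negative).
#' @examples
#' srp(60, 9) # 51
#' @export
srp <- function(rp_with_backup, rp_without_backup) {
  rp_with_backup - rp_without_backup
}

#' Survival period of a population
#'
#' The first year at which the census reaches zero; populations never
#' extinct within the horizon are right-censored at the horizon.
#'
#' @param counts Census counts indexed from year 0.
#' @param horizon Simulation horizon in years.
#' @return Years survived (integer-valued numeric).
#' @examples
#' survival_period(c(10, 4, 0, 0), horizon = 300) # 2
#' @export
survival_period <- function(counts, horizon) {
  z <- which(counts == 0)
  if (!length(z)) return(as.numeric(horizon))
  as.numeric(z[1L] - 1L)
}

#' Percentile placement of an observation among simulated values
#'
#' Mid-rank rule: 100 times the fraction of simulated values strictly below
#' the observation plus half the tied fraction. Symmetric and tie-robust.
#'
#' @param observed Observed value.
#' @param simulated Non-empty vector of simulated values.
#' @return Percentile in `[0, 100]`.
#' @examples
#' observed_percentile(0.5, c(0.2, 0.4, 0.6)) # 50
#' @export
observed_percentile <- function(observed, simulated) {
  if (!length(simulated)) .invalid_input("observed_percentile: simulated values empty")
  100 * (sum(simulated < observed) + 0.5 * sum(simulated == observed)) / length(simulated)
}

#' Per-year coverage of observations by the simulated band
#'
#' Flags, for each observed year, whether the observed parasitism ratio lies
#' within the min-max range of the simulated replicate values for that year.
#'
#' @param observed Data frame with columns `year` and `ratio`.
#' @param ensemble A [run_ensemble()] result.
#' @return Data frame: `year`, `observed`, `sim_min`, `sim_max`, `within`.
#' @export
band_coverage <- function(observed, ensemble) {
  stopifnot(inherits(ensemble, "bp_ensemble"))
  pr <- ensemble$pr # years x replicates matrix, rows = year 0..T
  yrs <- as.integer(rownames(pr))
  if (!all(observed$year %in% yrs)) {
    .invalid_input("band_coverage: observed year outside simulated years")
  }
  idx <- match(observed$year, yrs)
  smin <- apply(pr[idx, , drop = FALSE], 1L, min, na.rm = TRUE)
  smax <- apply(pr[idx, , drop = FALSE], 1L, max, na.rm = TRUE)
  data.frame(year = observed$year, observed = observed$ratio,
             sim_min = smin, sim_max = smax,
             within = observed$ratio >= smin & observed$ratio <= smax)
}
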