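# Domain state: species parameter blocks, individual tables, host pairing.
# Populations are stored as data frames (one row per bird) so the annual cycle
# can operate on whole cohorts with vectorized arithmetic.

# Behavioural probability keys per role. Mimicry and fertility are heritable
# only; the reinforced set additionally carries a "current" (experience-
# modified, non-heritable) value per individual.
.CUCKOO_KEYS <- c("lay_success", "mimic_color", "mimic_shape", "mimic_vocal", "fertility")
.HOST_KEYS <- c("nest_guard", "detect_color", "detect_shape", "detect_vocal", "fertility", "rearing")
.CUCKOO_REINFORCED <- "lay_success"
.HOST_REINFORCED <- c("nest_guard", "detect_color", "detect_shape", "detect_vocal", "rearing")
# Traits passed on by the mother alone (parasite egg appearance and call,
# plus the preferred host species); everything else is mid-parent.
.CUCKOO_MATERNAL <- c("mimic_color", "mimic_shape", "mimic_vocal")

.invalid_config <- function(msg) {
  stop(errorCondition(msg, class = c("bp_invalid_config", "error")))
}

#' Define a population-level parameter block for one species role
#'
#' Collects the demographic and behavioural parameters of either the parasite
#' (cuckoo) or the host: lifespan and clutch-size distributions, initial
#' population size, carrying capacity (hosts), behavioural probability means,
#' their standard deviations and the reinforcement increments. Standard
#' deviations and reinforcement increments default to two orders of magnitude
#' below the corresponding mean.
#'
#' @param role `"cuckoo"` or `"host"`.
#' @param lifespan_max,lifespan_mean Maximum and mean lifespan in years;
#'   individual lifespans are drawn from a truncated discretized Weibull on
#'   `[1, lifespan_max]` whose scale is solved so the truncated mean equals
#'   `lifespan_mean`. Alternatively pass `weibull_scale` directly (and omit
#'   `lifespan_mean`): the underlying hazard is then a fixed species property
#'   and `lifespan_max` acts purely as the truncation bound, so varying the
#'   maximum lifespan shifts the realized mean through truncation alone.
#' @param eggs_max,eggs_mean Maximum and mean egg capacity per female per
#'   year; capacities are drawn from a truncated Poisson on `[1, eggs_max]`
#'   whose rate is solved to match `eggs_mean`.
#' @param n_initial Initial population size (per host species for hosts).
#' @param capacity Carrying capacity K of logistic regulation (hosts only,
#'   per host species).
#' @param n_partner_species Number of host species (for cuckoos) or parasite
#'   species (for hosts).
#' @param prob_means Named numeric vector of behavioural probability means.
#'   Cuckoo keys: `lay_success` (successful laying in a host nest),
#'   `mimic_color`, `mimic_shape`, `mimic_vocal` (egg/chick mimicry),
#'   `fertility` (egg fertilization). Host keys: `nest_guard` (anti-laying
#'   defence), `detect_color`, `detect_shape`, `detect_vocal` (parasite
#'   detection), `fertility`, `rearing` (fledging success).
#' @param prob_sds Optional named vector of standard deviations; defaults to
#'   `prob_means / 100`.
#' @param reinforcement Optional named vector of reinforcement increments for
#'   the reinforced keys (cuckoo: `lay_success`; host: `nest_guard`,
#'   `detect_*`, `rearing`); defaults to `prob_means / 100`.
#' @param weibull_shape Shape of the lifespan Weibull (default 2).
#' @param weibull_scale Optional explicit Weibull scale; overrides
#'   `lifespan_mean`.
#' @return An object of class `bp_species`.
#' @export
species_params <- function(role = c("cuckoo", "host"),
                           lifespan_max, lifespan_mean = NULL,
                           eggs_max, eggs_mean,
                           n_initial,
                           capacity = NULL,
                           n_partner_species = 2L,
                           prob_means,
                           prob_sds = NULL,
                           reinforcement = NULL,
                           weibull_shape = 2,
                           weibull_scale = NULL) {
  role <- match.arg(role)
  keys <- if (role == "cuckoo") .CUCKOO_KEYS else .HOST_KEYS
  reinforced <- if (role == "cuckoo") .CUCKOO_REINFORCED else .HOST_REINFORCED
  missing_keys <- setdiff(keys, names(prob_means))
  if (length(missing_keys)) {
    .invalid_config(paste0("prob_means missing for ", role, ": ",
                           paste(missing_keys, collapse = ", ")))
  }
  prob_means <- prob_means[keys]
  if (any(prob_means < 0 | prob_means > 1)) {
    bad <- keys[prob_means < 0 | prob_means > 1][1]
    .invalid_config(paste0("prob_means.", bad, " outside [0, 1]"))
  }
  if (is.null(prob_sds)) prob_sds <- prob_means / 100
  prob_sds <- prob_sds[keys]
  if (anyNA(prob_sds)) .invalid_config("prob_sds must cover every probability key")
  if (any(prob_sds < 0)) .invalid_config("prob_sds must be >= 0")
  if (is.null(reinforcement)) reinforcement <- (prob_means / 100)[reinforced]
  reinforcement <- reinforcement[reinforced]
  if (anyNA(reinforcement) || any(reinforcement < 0)) {
    .invalid_config("reinforcement increments must be >= 0 for every reinforced key")
  }
  if (is.null(weibull_scale)) {
    if (is.null(lifespan_mean)) .invalid_config("give lifespan_mean or weibull_scale")
    if (lifespan_mean > lifespan_max || lifespan_mean < 1) {
      .invalid_config("lifespan_mean must lie in [1, lifespan_max]")
    }
    weibull_scale <- weibull_scale_for_mean(lifespan_mean, weibull_shape,
                                            1L, lifespan_max)
  } else if (weibull_scale <= 0) {
    .invalid_config("weibull_scale must be > 0")
  }
  realized_mean <- sum((1:lifespan_max) *
                         .weibull_trunc_pmf(weibull_shape, weibull_scale, 1L, lifespan_max))
  if (eggs_mean > eggs_max || eggs_mean < 1) {
    .invalid_config("eggs_mean must lie in [1, eggs_max]")
  }
  if (n_initial < 0) .invalid_config("n_initial must be >= 0")
  if (role == "host") {
    if (is.null(capacity) || capacity <= 0) .invalid_config("hosts need capacity > 0")
    if (capacity < n_initial) .invalid_config("capacity must be >= n_initial")
  }
  structure(list(
    role = role,
    lifespan_max = as.integer(lifespan_max),
    lifespan_mean = realized_mean,
    eggs_max = as.integer(eggs_max),
    eggs_mean = eggs_mean,
    n_initial = as.integer(n_initial),
    capacity = if (is.null(capacity)) NULL else as.integer(capacity),
    n_partner_species = as.integer(n_partner_species),
    prob_means = prob_means,
    prob_sds = prob_sds,
    reinforcement = reinforcement,
    weibull_shape = weibull_shape,
    weibull_scale = weibull_scale,
    pois_rate = .pois_rate_for_mean(eggs_mean, 1L, eggs_max)
  ), class = "bp_species")
}

#' @export
print.bp_species <- function(x, ...) {
  cat("<bp_species> role:", x$role,
      "| lifespan", x$lifespan_mean, "/", x$lifespan_max,
      "| eggs", x$eggs_mean, "/", x$eggs_max,
      "| n0", x$n_initial,
      if (!is.null(x$capacity)) paste("| K", x$capacity) else "", "\n")
  print(round(x$prob_means, 4))
  invisible(x)
}

.reinforced_keys <- function(params) {
  if (params$role == "cuckoo") .CUCKOO_REINFORCED else .HOST_REINFORCED
}

#' Initialize a population of individuals
#'
#' Draws `n` individuals from a species parameter block: sexes uniform,
#' lifespans from the truncated Weibull on `[1, lifespan_max]`, egg capacities
#' from the truncated Poisson on `[1, eggs_max]`, every behavioural trait from
#' a truncated normal on `[0, 1]`, initial ages uniform over the years an
#' individual of its lifespan can be alive, and (for female cuckoos) a
#' preferred host species uniform over the host species.
#'
#' @param params A [species_params()] block.
#' @param n Number of individuals (default `params$n_initial`).
#' @param group Integer label attached to every individual (cuckoo group id).
#' @return A data frame, one row per individual, with columns `id`, `sex`,
#'   `age`, `lifespan`, `eggs`, one `trait_*` column per behavioural
#'   probability, a `cur_*` column per reinforced probability (initialized at
#'   the heritable value), and for cuckoos `group` and `pref`.
#' @export
init_population <- function(params, n = params$n_initial, group = 1L) {
  stopifnot(inherits(params, "bp_species"))
  n <- as.integer(n)
  if (n < 0) .invalid_config("n must be >= 0")
  keys <- if (params$role == "cuckoo") .CUCKOO_KEYS else .HOST_KEYS
  lifespan <- sample_truncated_weibull(n, params$weibull_shape, params$weibull_scale,
                                       1L, params$lifespan_max)
  pop <- data.frame(
    id = seq_len(n),
    sex = if (n) sample(c("F", "M"), n, replace = TRUE) else character(0),
    age = if (n) as.integer(floor(stats::runif(n) * lifespan)) else integer(0),
    lifespan = lifespan,
    eggs = sample_truncated_poisson(n, params$pois_rate, 1L, params$eggs_max),
    stringsAsFactors = FALSE
  )
  for (k in keys) {
    pop[[paste0("trait_", k)]] <-
      sample_truncated_normal(n, params$prob_means[[k]], params$prob_sds[[k]], 0, 1)
  }
  for (k in .reinforced_keys(params)) {
    pop[[paste0("cur_", k)]] <- pop[[paste0("trait_", k)]]
  }
  if (params$role == "cuckoo") {
    pop$group <- rep.int(as.integer(group), n)
    pop$pref <- rep.int(NA_integer_, n)
    fem <- pop$sex == "F"
    pop$pref[fem] <- sample.int(params$n_partner_species, sum(fem), replace = TRUE)
  }
  pop
}

#' Randomly pair hosts into monogamous reproductive units
#'
#' Pairs `min(#females, #males)` birds by a uniformly random bijection; the
#' surplus sex stays unpaired and does not breed this year.
#'
#' @param pop A host population data frame (rows are individuals).
#' @return A list with `pairs` (data frame of row indices `f`, `m`) and
#'   `unpaired` (row indices of birds left without a partner).
#' @export
make_pairs <- function(pop) {
  fem <- which(pop$sex == "F")
  mal <- which(pop$sex == "M")
  np <- min(length(fem), length(mal))
  if (np > 0) {
    pf <- if (length(fem) == 1L) fem else sample(fem)
    pm <- if (length(mal) == 1L) mal else sample(mal)
    f <- pf[seq_len(np)]
    m <- pm[seq_len(np)]
    unpaired <- c(pf[-seq_len(np)], pm[-seq_len(np)])
  } else {
    f <- integer(0); m <- integer(0)
    unpaired <- c(fem, mal)
  }
  list(pairs = data.frame(f = f, m = m), unpaired = unpaired)
}
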