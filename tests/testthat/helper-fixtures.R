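# Small configurations used across the test files. Tiny populations and short
# horizons keep unit tests fast; the acceptance tests use the packaged
# fixtures at full scale.

tiny_cuckoo <- function(n = 20, ...) {
  args <- utils::modifyList(list(
    role = "cuckoo", lifespan_max = 10L, lifespan_mean = 6,
    eggs_max = 8L, eggs_mean = 4, n_initial = n, n_partner_species = 2L,
    weibull_shape = 3,
    prob_means = c(lay_success = 0.65, mimic_color = 0.15, mimic_shape = 0.15,
                   mimic_vocal = 0.20, fertility = 0.75)
  ), list(...))
  do.call(species_params, args)
}

tiny_host <- function(n = 40, capacity = max(120L, 3L * n), ...) {
  args <- utils::modifyList(list(
    role = "host", lifespan_max = 4L, lifespan_mean = 3,
    eggs_max = 7L, eggs_mean = 4.2, n_initial = n, capacity = capacity,
    n_partner_species = 1L, weibull_shape = 3,
    prob_means = c(nest_guard = 0.30, detect_color = 0.40, detect_shape = 0.40,
                   detect_vocal = 0.30, fertility = 0.75, rearing = 0.75)
  ), list(...))
  do.call(species_params, args)
}

tiny_config <- function(n_cuckoo = 20, n_host = 40, backup = TRUE, ...) {
  bp_config(tiny_cuckoo(n_cuckoo), tiny_host(n_host), backup = backup, ...)
}

# Mean of a normal distribution truncated to [low, high]: the closed-form
# oracle used to check the acceptance-rejection sampler.
truncnorm_mean <- function(mean, sd, low = 0, high = 1) {
  a <- (low - mean) / sd
  b <- (high - mean) / sd
  mean + sd * (stats::dnorm(a) - stats::dnorm(b)) / (stats::pnorm(b) - stats::pnorm(a))
}

# Inverse-CDF sampler for the truncated normal: the independent sampling
# route used in distribution-equivalence checks.
truncnorm_icdf <- function(n, mean, sd, low = 0, high = 1) {
  pa <- stats::pnorm(low, mean, sd)
  pb <- stats::pnorm(high, mean, sd)
  stats::qnorm(pa + stats::runif(n) * (pb - pa), mean, sd)
}
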