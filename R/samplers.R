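# Bounded stochastic sampling primitives. Every sampler draws from a parent
# distribution and resamples until the draw falls inside the truncation
# support (acceptance-rejection), so the result follows the parent density
# renormalized on [low, high]. A retry cap guards specs whose acceptance mass
# is (near) zero.

.AR_MAX_ROUNDS <- 10000L

.invalid_spec <- function(msg) {
  stop(errorCondition(msg, class = c("bp_invalid_spec", "error")))
}

# Vectorized acceptance-rejection driver: `draw(idx)` proposes one value per
# remaining index; proposals outside [low, high] are redrawn.
.ar_sample <- function(n, draw, low, high) {
  out <- numeric(n)
  need <- seq_len(n)
  rounds <- 0L
  while (length(need)) {
    if (rounds >= .AR_MAX_ROUNDS) {
      .invalid_spec("acceptance-rejection retry cap reached; truncation support has (near) zero probability mass")
    }
    prop <- draw(need)
    ok <- prop >= low[need] & prop <= high[need]
    out[need[ok]] <- prop[ok]
    need <- need[!ok]
    rounds <- rounds + 1L
  }
  out
}

#' Sample from a truncated normal distribution
#'
#' Draws by acceptance-rejection: normal proposals are resampled until they
#' fall in `[low, high]`. Used for all probability-valued parameters
#' (laying/parasitism success, mimicry, detection, fertility, rearing) and for
#' trait inheritance. With `sd = 0` the sampler degenerates to the constant
#' `mean` (which must then lie inside the support). Deep-tail truncations
#' (support mass below 1e-3) switch to inverse-CDF draws from the same
#' renormalized distribution, which rejection sampling cannot reach within the
#' retry cap; a support with no numerical mass at all is an error.
#'
#' @param n Number of draws.
#' @param mean Mean(s) of the parent normal; recycled to length `n`.
#' @param sd Standard deviation(s), `>= 0`; recycled to length `n`.
#' @param low,high Truncation bounds, `low <= high`; recycled to length `n`.
#' @return Numeric vector of length `n`, every element in `[low, high]`.
#' @examples
#' sample_truncated_normal(5, mean = 0.4, sd = 0.004)
#' @export
sample_truncated_normal <- function(n, mean, sd, low = 0, high = 1) {
  mean <- rep_len(as.numeric(mean), n)
  sd <- rep_len(as.numeric(sd), n)
  low <- rep_len(as.numeric(low), n)
  high <- rep_len(as.numeric(high), n)
  if (any(low > high)) .invalid_spec("truncated normal: low > high")
  if (any(sd < 0)) .invalid_spec("truncated normal: sd < 0")
  out <- numeric(n)
  degen <- sd == 0
  if (any(degen)) {
    if (any(mean[degen] < low[degen] | mean[degen] > high[degen])) {
      .invalid_spec("truncated normal: sd = 0 with mean outside [low, high]")
    }
    out[degen] <- mean[degen]
  }
  if (any(!degen)) {
    idx <- which(!degen)
    # deep-tail truncations would exhaust the rejection cap; those draws use
    # the inverse CDF of the same renormalized distribution instead
    mass <- stats::pnorm(high[idx], mean[idx], sd[idx]) -
      stats::pnorm(low[idx], mean[idx], sd[idx])
    if (any(mass <= 0)) {
      .invalid_spec("truncated normal: support carries no probability mass")
    }
    tail_i <- idx[mass < 1e-3]
    ar_i <- setdiff(idx, tail_i)
    if (length(ar_i)) {
      out[ar_i] <- .ar_sample(length(ar_i),
                              function(k) stats::rnorm(length(k), mean[ar_i][k], sd[ar_i][k]),
                              low[ar_i], high[ar_i])
    }
    if (length(tail_i)) {
      pa <- stats::pnorm(low[tail_i], mean[tail_i], sd[tail_i])
      pb <- stats::pnorm(high[tail_i], mean[tail_i], sd[tail_i])
      q <- stats::qnorm(pa + stats::runif(length(tail_i)) * (pb - pa),
                        mean[tail_i], sd[tail_i])
      out[tail_i] <- pmin(pmax(q, low[tail_i]), high[tail_i])
    }
  }
  out
}

#' Sample integers from a truncated, discretized Weibull distribution
#'
#' Long-tailed discrete variables (lifespans) are modelled by drawing a
#' continuous Weibull variate, rounding to the nearest integer, and accepting
#' the draw only if it lies in `{low, ..., high}`. The rounding happens before
#' the acceptance test, so the result follows the discretized Weibull pmf
#' renormalized on the support.
#'
#' @param n Number of draws.
#' @param shape,scale Weibull shape and scale, both `> 0`.
#' @param low,high Integer truncation bounds, `1 <= low <= high`.
#' @return Integer vector of length `n` in `[low, high]`.
#' @examples
#' sample_truncated_weibull(5, shape = 2, scale = 3, low = 1, high = 10)
#' @export
sample_truncated_weibull <- function(n, shape, scale, low = 1L, high) {
  if (any(shape <= 0) || any(scale <= 0)) .invalid_spec("truncated Weibull: shape and scale must be > 0")
  low <- rep_len(as.numeric(low), n)
  high <- rep_len(as.numeric(high), n)
  if (any(low > high)) .invalid_spec("truncated Weibull: low > high")
  if (any(low < 1)) .invalid_spec("truncated Weibull: low must be >= 1")
  shape <- rep_len(as.numeric(shape), n)
  scale <- rep_len(as.numeric(scale), n)
  out <- .ar_sample(n,
                    function(k) round(stats::rweibull(length(k), shape[k], scale[k])),
                    low, high)
  as.integer(out)
}

#' Sample integers from a truncated Poisson distribution
#'
#' Bounded count variables (clutch sizes, egg capacities) are drawn from a
#' Poisson distribution by acceptance-rejection on `{low, ..., high}`.
#'
#' @param n Number of draws.
#' @param rate Poisson rate, `> 0`.
#' @param low,high Integer truncation bounds, `0 <= low <= high`.
#' @return Integer vector of length `n` in `[low, high]`.
#' @examples
#' sample_truncated_poisson(5, rate = 4, low = 1, high = 8)
#' @export
sample_truncated_poisson <- function(n, rate, low = 0L, high) {
  if (any(rate <= 0)) .invalid_spec("truncated Poisson: rate must be > 0")
  low <- rep_len(as.numeric(low), n)
  high <- rep_len(as.numeric(high), n)
  if (any(low > high)) .invalid_spec("truncated Poisson: low > high")
  if (any(low < 0)) .invalid_spec("truncated Poisson: low must be >= 0")
  rate <- rep_len(as.numeric(rate), n)
  out <- .ar_sample(n,
                    function(k) stats::rpois(length(k), rate[k]),
                    low, high)
  as.integer(out)
}

#' Draw an offspring trait value from its parents
#'
#' Offspring trait probabilities are drawn from a truncated normal centred on
#' the mother's heritable value (maternally inherited traits, e.g. parasite
#' egg colour and shape) or on the mid-parent value (biparental traits).
#' Reinforcement-modified values are never passed here: inheritance acts on
#' heritable trait values only.
#'
#' @param mother Mother's heritable trait value(s).
#' @param father Father's heritable trait value(s), or `NULL` for maternal
#'   inheritance.
#' @param maternal If `TRUE`, the offspring mean is the mother's value alone.
#' @param sd Inheritance standard deviation (the small trait variation).
#' @param low,high Truncation bounds, default the probability interval.
#' @return Numeric vector of offspring trait values in `[low, high]`.
#' @examples
#' inherit_trait(0.2, 0.4, maternal = FALSE, sd = 0) # mid-parent 0.3
#' @export
inherit_trait <- function(mother, father = NULL, maternal = TRUE, sd, low = 0, high = 1) {
  if (!maternal && is.null(father)) {
    stop(errorCondition("biparental inheritance requires a father value",
                        class = c("bp_invalid_call", "error")))
  }
  centre <- if (maternal) mother else (mother + father) / 2
  sample_truncated_normal(length(centre), centre, sd, low, high)
}

#' Describe a truncated sampling distribution
#'
#' A small spec object naming one of the four stochastic families used for
#' initialization: uniform (categorical), truncated normal, truncated Weibull
#' and truncated Poisson.
#'
#' @param family One of `"normal"`, `"weibull"`, `"poisson"`, `"uniform"`.
#' @param location Mean (normal), scale (Weibull) or rate (Poisson).
#' @param dispersion Sd (normal) or shape (Weibull); unused otherwise.
#' @param low,high Truncation bounds.
#' @param integer_valued Whether draws are integers.
#' @return An object of class `bp_trunc_spec`.
#' @export
trunc_spec <- function(family = c("normal", "weibull", "poisson", "uniform"),
                       location = 0, dispersion = 0, low, high,
                       integer_valued = family != "normal") {
  family <- match.arg(family)
  if (low > high) .invalid_spec("trunc_spec: low > high")
  if (dispersion < 0) .invalid_spec("trunc_spec: dispersion < 0")
  if (integer_valued && (low != round(low) || high != round(high))) {
    .invalid_spec("trunc_spec: integer-valued spec needs integer bounds")
  }
  structure(list(family = family, location = location, dispersion = dispersion,
                 low = low, high = high, integer_valued = integer_valued),
            class = "bp_trunc_spec")
}

#' Sample from a truncated distribution spec
#'
#' @param spec A [trunc_spec()].
#' @param n Number of draws.
#' @return Numeric or integer vector of length `n` inside the support.
#' @export
sample_trunc <- function(spec, n) {
  stopifnot(inherits(spec, "bp_trunc_spec"))
  switch(spec$family,
    normal = sample_truncated_normal(n, spec$location, spec$dispersion, spec$low, spec$high),
    weibull = sample_truncated_weibull(n, spec$dispersion, spec$location, spec$low, spec$high),
    poisson = sample_truncated_poisson(n, spec$location, spec$low, spec$high),
    uniform = sample.int(spec$high - spec$low + 1L, n, replace = TRUE) + as.integer(spec$low) - 1L
  )
}

# pmf of the discretized Weibull (round-to-nearest) renormalized on low..high.
.weibull_trunc_pmf <- function(shape, scale, low, high) {
  k <- low:high
  p <- stats::pweibull(k + 0.5, shape, scale) - stats::pweibull(pmax(k - 0.5, 0), shape, scale)
  p / sum(p)
}

.pois_trunc_pmf <- function(rate, low, high) {
  k <- low:high
  p <- stats::dpois(k, rate)
  p / sum(p)
}

#' Solve the Weibull scale matching a target truncated mean
#'
#' The model configures mean lifespans, but the Weibull family is parametrized
#' by shape and scale. Given a shape, this solves for the scale whose
#' truncated, discretized Weibull distribution on `[low, high]` has the target
#' mean, so that configured mean lifespans are honoured exactly.
#'
#' @param mean_target Desired mean of the truncated discretized draw.
#' @param shape Weibull shape (default 2, a mild right skew typical of avian
#'   lifespan distributions).
#' @param low,high Integer truncation bounds.
#' @return The Weibull scale (numeric scalar).
#' @export
weibull_scale_for_mean <- function(mean_target, shape = 2, low = 1L, high) {
  if (mean_target < low || mean_target > high) {
    .invalid_spec("weibull_scale_for_mean: target mean outside [low, high]")
  }
  if (low == high) return(as.numeric(low))
  k <- low:high
  f <- function(scale) {
    p <- stats::pweibull(k + 0.5, shape, scale) - stats::pweibull(pmax(k - 0.5, 0), shape, scale)
    if (sum(p) <= 0) return(low - mean_target) # all mass below the support
    sum(k * p / sum(p)) - mean_target
  }
  upper <- high * 20
  if (f(upper) < 0) {
    .invalid_spec("weibull_scale_for_mean: target mean not attainable on [low, high] with this shape (increase the shape)")
  }
  stats::uniroot(f, lower = 1e-3, upper = upper, tol = 1e-9)$root
}

# Poisson rate whose truncated mean on low..high equals the target.
.pois_rate_for_mean <- function(mean_target, low, high) {
  if (mean_target < low || mean_target > high) {
    .invalid_spec("poisson rate: target mean outside [low, high]")
  }
  if (low == high) return(max(as.numeric(low), 1e-6))
  f <- function(rate) sum((low:high) * .pois_trunc_pmf(rate, low, high)) - mean_target
  stats::uniroot(f, lower = 1e-6, upper = high * 20, tol = 1e-9)$root
}
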