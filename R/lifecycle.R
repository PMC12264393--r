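# The annual simulation cycle: pairing -> clutches -> parasite egg generation
# -> parasitism (with preferred-host targeting and back-up switching) -> nest
# resolution (detection, fertilization filter, vocal-password rejection,
# abandonment/re-nesting, logistic-regulated rearing) -> reinforcement ->
# cohort turnover. State lives in plain data frames; each step is vectorized
# over nests or individuals except the inherently sequential egg-placement
# loop, where cuckoos contend for unparasitized nests.

#' Non-negative difference of two probabilities
#'
#' The net probability of an attacker beating a defender on one behavioural
#' channel: `max(0, p_attacker - p_defender)`. Used for laying vs
#' nest-guarding, mimicry vs detection, and vocal mimicry vs vocal rejection.
#'
#' @param p_attacker,p_defender Probabilities in `[0, 1]` (vectorized).
#' @return `pmax(0, p_attacker - p_defender)`.
#' @examples
#' clipped_difference(0.40, 0.15) # 0.25
#' clipped_difference(0.15, 0.40) # 0
#' @export
clipped_difference <- function(p_attacker, p_defender) {
  pmax(0, p_attacker - p_defender)
}

#' Probability that a host pair detects and rejects a parasite egg
#'
#' Colour and shape are inspected independently; the egg escapes on a channel
#' when the cuckoo's mimicry meets or exceeds the pair's detection, and is
#' rejected if either channel catches it:
#' `1 - (1 - max(0, d_c - m_c)) * (1 - max(0, d_s - m_s))`.
#'
#' @param detect_color,detect_shape Host pair detection probabilities.
#' @param mimic_color,mimic_shape Parasite egg mimicry probabilities.
#' @return Detection probability in `[0, 1]` (vectorized).
#' @examples
#' egg_detection_probability(0.40, 0.15, 0.40, 0.15) # 0.4375
#' @export
egg_detection_probability <- function(detect_color, mimic_color,
                                      detect_shape, mimic_shape) {
  1 - (1 - clipped_difference(detect_color, mimic_color)) *
      (1 - clipped_difference(detect_shape, mimic_shape))
}

#' Logistic population-regulation coefficient
#'
#' Rearing success is multiplied by `max(0, 1 - n/K)`, the linear density
#' dependence of logistic growth: 1 in an empty habitat, 0 at carrying
#' capacity.
#'
#' @param n_current Current adult census of the rearing host species.
#' @param capacity Carrying capacity K, `> 0`.
#' @return Factor in `[0, 1]`.
#' @export
regulation_coefficient <- function(n_current, capacity) {
  if (any(capacity <= 0)) .invalid_config("regulation: capacity must be > 0")
  pmax(0, 1 - n_current / capacity)
}

#' Apply an experience-driven reinforcement increment
#'
#' A reinforced behavioural probability is increased by its increment and
#' capped at 1: `p(t+1) = min(1, p(t) + delta)`. Reinforcement modifies the
#' individual's current (expressed) value only; heritable trait values are
#' untouched, so reinforcement is never transmitted to offspring.
#'
#' @param p Current probability value(s).
#' @param delta Reinforcement increment(s), `>= 0`.
#' @return Updated probability value(s) in `[0, 1]`.
#' @examples
#' apply_reinforcement(0.40, 0.004) # 0.404
#' apply_reinforcement(0.999, 0.004) # 1
#' @export
apply_reinforcement <- function(p, delta) {
  pmin(1, p + delta)
}

# ---- internal year machinery -------------------------------------------------

# data.frame assembly / row subsetting without the validation overhead of the
# public constructors; all callers guarantee equal column lengths
.fast_df <- function(lst) {
  structure(lst, class = "data.frame",
            row.names = .set_row_names(length(lst[[1L]])))
}

.subset_rows <- function(df, keep) {
  .fast_df(lapply(df, `[`, keep))
}

# One nest per pair; pair-level probabilities are the arithmetic mean of the
# two members' values (current values for reinforced keys).
.build_nests <- function(host_df, pairs, renest = 0L) {
  f <- pairs$f
  m <- pairs$m
  .fast_df(list(
    f = f, m = m,
    clutch = host_df$eggs[f],
    guard = (host_df$cur_nest_guard[f] + host_df$cur_nest_guard[m]) / 2,
    dcol = (host_df$cur_detect_color[f] + host_df$cur_detect_color[m]) / 2,
    dshp = (host_df$cur_detect_shape[f] + host_df$cur_detect_shape[m]) / 2,
    dvoc = (host_df$cur_detect_vocal[f] + host_df$cur_detect_vocal[m]) / 2,
    fert = (host_df$trait_fertility[f] + host_df$trait_fertility[m]) / 2,
    rear = (host_df$cur_rearing[f] + host_df$cur_rearing[m]) / 2,
    renest = rep.int(as.integer(renest), length(f)),
    par = rep.int(0L, length(f)),
    attempted = rep.int(FALSE, length(f))
  ))
}

#' Build the host clutches (nests) for one species' breeding season
#'
#' Each pair builds one nest and lays as many eggs as the female's annual egg
#' capacity. Pair-level probabilities are the mean of the two members'
#' expressed values.
#'
#' @param host_df Host population data frame.
#' @param pairs Pair table from [make_pairs()].
#' @return A nest data frame (one row per nest) used by [resolve_nests()].
#' @export
generate_host_clutches <- function(host_df, pairs) {
  .build_nests(host_df, pairs)
}

#' Generate the season's parasite eggs
#'
#' Every female cuckoo mates with multiple males of her group (one sire drawn
#' uniformly per egg) and produces eggs up to her egg capacity; with no living
#' male in the group she produces none. Egg colour, shape and vocal mimicry
#' and the preferred host species are inherited from the mother alone; laying
#' success and fertility are mid-parent. All inherited values are drawn from
#' truncated normals around the heritable parental values.
#'
#' @param cuckoos Cuckoo population data frame.
#' @param group_params List of cuckoo [species_params()], one per group.
#' @return An egg data frame (one row per egg) with trait columns, the
#'   mother's row index, her fertility (the egg's fertilization probability)
#'   and the inherited host preference.
#' @export
generate_cuckoo_eggs <- function(cuckoos, group_params) {
  out <- vector("list", length(group_params))
  for (g in seq_along(group_params)) {
    p <- group_params[[g]]
    rows <- which(cuckoos$group == g)
    fem <- rows[cuckoos$sex[rows] == "F"]
    mal <- rows[cuckoos$sex[rows] == "M"]
    if (!length(fem) || !length(mal)) next
    counts <- cuckoos$eggs[fem]
    mother <- rep.int(fem, counts)
    tot <- length(mother)
    if (!tot) next
    sire <- mal[sample.int(length(mal), tot, replace = TRUE)]
    sds <- p$prob_sds
    out[[g]] <- .fast_df(list(
      mother = mother,
      group = rep.int(g, tot),
      pref = cuckoos$pref[mother],
      sex = sample(c("F", "M"), tot, replace = TRUE),
      mimic_color = inherit_trait(cuckoos$trait_mimic_color[mother],
                                  sd = sds[["mimic_color"]]),
      mimic_shape = inherit_trait(cuckoos$trait_mimic_shape[mother],
                                  sd = sds[["mimic_shape"]]),
      mimic_vocal = inherit_trait(cuckoos$trait_mimic_vocal[mother],
                                  sd = sds[["mimic_vocal"]]),
      lay_success = inherit_trait(cuckoos$trait_lay_success[mother],
                                  cuckoos$trait_lay_success[sire],
                                  maternal = FALSE, sd = sds[["lay_success"]]),
      fertility = inherit_trait(cuckoos$trait_fertility[mother],
                                cuckoos$trait_fertility[sire],
                                maternal = FALSE, sd = sds[["fertility"]]),
      mother_fertility = cuckoos$trait_fertility[mother]
    ))
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    return(data.frame(mother = integer(0), group = integer(0), pref = integer(0),
                      sex = character(0), mimic_color = numeric(0),
                      mimic_shape = numeric(0), mimic_vocal = numeric(0),
                      lay_success = numeric(0), fertility = numeric(0),
                      mother_fertility = numeric(0)))
  }
  do.call(rbind, out)
}

#' Run one parasitism pass over the season's nests
#'
#' Female cuckoos are processed in uniformly random order; each places her
#' eggs one at a time. An egg targets a uniformly chosen unparasitized nest of
#' the mother's preferred host species; if that species has none left and
#' back-up behaviour is enabled, a uniformly chosen alternative species with
#' unparasitized nests is used instead. With no target anywhere the egg stays
#' unlaid (and may be used on re-nests later in the year). Given a target,
#' laying succeeds with probability `max(0, lay_success - nest_guard)`; on
#' success the parasite egg replaces one host egg and the nest becomes
#' unavailable to other cuckoos. Every targeted nest counts as an experienced
#' laying attempt for the pair's nest-guard reinforcement, successful or not.
#'
#' @param eggs Egg table from [generate_cuckoo_eggs()].
#' @param egg_rows Which egg rows take part in this pass.
#' @param nests_list List of nest data frames, one per host species.
#' @param cuckoos Cuckoo population data frame.
#' @param backup Whether back-up host switching is enabled.
#' @return List: updated `nests_list`, `leftover` (egg rows that found no
#'   target), `laid_mothers` (unique mother rows with a successful lay).
#' @export
run_parasitism <- function(eggs, egg_rows, nests_list, cuckoos, backup = TRUE) {
  nhs <- length(nests_list)
  avail <- lapply(nests_list, function(ns) which(ns$par == 0L))
  cnt <- vapply(avail, length, integer(1))
  par_v <- lapply(nests_list, function(ns) ns$par)
  att_v <- lapply(nests_list, function(ns) ns$attempted)
  guard_v <- lapply(nests_list, function(ns) ns$guard)
  clutch_v <- lapply(nests_list, function(ns) ns$clutch)

  # shuffle females, keep each female's eggs consecutive
  mothers <- eggs$mother[egg_rows]
  fem <- unique(mothers)
  if (length(fem) > 1L) fem <- sample(fem)
  ord <- egg_rows[order(match(mothers, fem))]

  # pre-drawn uniforms for nest choice, back-up species choice and the
  # laying Bernoulli (at most one of each per egg)
  u_nest <- stats::runif(length(ord))
  u_bu <- stats::runif(length(ord))
  u_lay <- stats::runif(length(ord))
  pref_v <- eggs$pref
  mom_v <- eggs$mother
  lay_v <- cuckoos$cur_lay_success

  leftover <- integer(0)
  laid_mothers <- integer(0)
  step <- 0L
  for (i in ord) {
    step <- step + 1L
    s <- pref_v[i]
    if (is.na(s) || s < 1L || s > nhs) s <- 1L
    if (cnt[s] == 0L) {
      if (backup) {
        cand <- which(cnt > 0L)
        cand <- cand[cand != s]
        if (!length(cand)) { leftover <- c(leftover, i); next }
        s <- cand[floor(u_bu[step] * length(cand)) + 1L]
      } else {
        leftover <- c(leftover, i)
        next
      }
    }
    k <- floor(u_nest[step] * cnt[s]) + 1L
    j <- avail[[s]][k]
    att_v[[s]][j] <- TRUE
    mom <- mom_v[i]
    p_lay <- lay_v[mom] - guard_v[[s]][j]
    if (p_lay > 0 && u_lay[step] < p_lay) {
      par_v[[s]][j] <- i
      clutch_v[[s]][j] <- max(0L, clutch_v[[s]][j] - 1L) # parasite replaces a host egg
      avail[[s]][k] <- avail[[s]][cnt[s]]
      cnt[s] <- cnt[s] - 1L
      laid_mothers <- c(laid_mothers, mom)
    }
  }
  for (s in seq_len(nhs)) {
    nests_list[[s]]$par <- par_v[[s]]
    nests_list[[s]]$attempted <- att_v[[s]]
    nests_list[[s]]$clutch <- clutch_v[[s]]
  }
  list(nests_list = nests_list, leftover = leftover,
       laid_mothers = unique(laid_mothers))
}

#' Resolve nests to their terminal state and fledgling counts
#'
#' Applies the incubation/rearing sequence to every nest: (i) a parasitized
#' nest's egg is detected with the colour/shape detection probability and, if
#' detected, removed (the host clutch proceeds); (ii) the fertilization filter
#' keeps the parasite egg with the laying female's fertility and each host egg
#' with the pair's fertility; (iii) a hatched parasite chick is rejected via
#' the vocal password with probability `max(0, detect_vocal - mimic_vocal)` —
#' on rejection the pair abandons the nest and everything in it; on a miss the
#' chick kills all host nestlings and is reared alone; (iv) each surviving
#' nestling fledges with the pair's rearing probability times the host
#' species' regulation coefficient.
#'
#' Every resolved nest lands in exactly one of four states: `nonparasitized`,
#' `parasitized_detected`, `parasitized_unfertilized`, `parasitized_hatched`.
#'
#' @param nests Nest data frame for one host species.
#' @param eggs Parasite egg table (referenced by `nests$par`).
#' @param reg Regulation coefficient of this host species this year.
#' @return List with `state` (factor of the four nest states), `host_fledge`
#'   (integer per nest), `cuckoo_fledged_egg` (egg rows that fledged),
#'   `abandoned` (vocal-rejection abandonments), `deceived` (pairs that reared
#'   a parasite chick).
#' @export
resolve_nests <- function(nests, eggs, reg) {
  n <- nrow(nests)
  state <- rep.int("nonparasitized", n)
  par <- nests$par
  hp <- par > 0L
  detected <- logical(n)
  if (any(hp)) {
    dp <- egg_detection_probability(nests$dcol[hp], eggs$mimic_color[par[hp]],
                                    nests$dshp[hp], eggs$mimic_shape[par[hp]])
    detected[hp] <- stats::runif(sum(hp)) < dp
  }
  state[hp & detected] <- "parasitized_detected"
  undet <- hp & !detected
  fert_ok <- logical(n)
  if (any(undet)) {
    fert_ok[undet] <- stats::runif(sum(undet)) < eggs$mother_fertility[par[undet]]
  }
  state[undet & !fert_ok] <- "parasitized_unfertilized"
  hatched <- undet & fert_ok
  state[hatched] <- "parasitized_hatched"
  vdet <- logical(n)
  if (any(hatched)) {
    vrej <- clipped_difference(nests$dvoc[hatched], eggs$mimic_vocal[par[hatched]])
    vdet[hatched] <- stats::runif(sum(hatched)) < vrej
  }
  abandoned <- vdet
  reared_cuckoo <- hatched & !vdet
  p_fledge <- pmin(1, pmax(0, nests$fert * nests$rear * reg))
  eligible <- !abandoned & !reared_cuckoo
  host_fledge <- integer(n)
  if (any(eligible)) {
    host_fledge[eligible] <- stats::rbinom(sum(eligible), nests$clutch[eligible],
                                           p_fledge[eligible])
  }
  cuckoo_ok <- logical(n)
  if (any(reared_cuckoo)) {
    p_c <- pmin(1, pmax(0, nests$rear[reared_cuckoo] * reg))
    cuckoo_ok[reared_cuckoo] <- stats::runif(sum(reared_cuckoo)) < p_c
  }
  list(state = factor(state, levels = c("nonparasitized", "parasitized_detected",
                                        "parasitized_unfertilized",
                                        "parasitized_hatched")),
       host_fledge = host_fledge,
       cuckoo_fledged_egg = par[cuckoo_ok],
       abandoned = abandoned,
       deceived = reared_cuckoo)
}

# Host fledglings for one species: biparental truncated-normal inheritance
# around the pair's heritable trait values, drawn only for eggs that fledge
# (Bernoulli fates are independent of trait values, so the fledgling trait
# distribution is unchanged by sampling lazily).
.host_recruits <- function(host_df, nests, host_fledge, params) {
  idx <- rep.int(seq_len(nrow(nests)), host_fledge)
  n <- length(idx)
  if (!n) return(NULL)
  f <- nests$f[idx]
  m <- nests$m[idx]
  sds <- params$prob_sds
  rec <- .fast_df(list(
    id = rep.int(NA_integer_, n),
    sex = sample(c("F", "M"), n, replace = TRUE),
    age = rep.int(0L, n),
    lifespan = sample_truncated_weibull(n, params$weibull_shape, params$weibull_scale,
                                        1L, params$lifespan_max),
    eggs = sample_truncated_poisson(n, params$pois_rate, 1L, params$eggs_max)
  ))
  for (k in .HOST_KEYS) {
    tk <- paste0("trait_", k)
    rec[[tk]] <- inherit_trait(host_df[[tk]][f], host_df[[tk]][m],
                               maternal = FALSE, sd = sds[[k]])
  }
  for (k in .HOST_REINFORCED) {
    rec[[paste0("cur_", k)]] <- rec[[paste0("trait_", k)]]
  }
  rec
}

# Cuckoo recruits from fledged parasite eggs; lifespan/egg capacity are drawn
# at recruitment from the group's parameters.
.cuckoo_recruits <- function(eggs, egg_rows, group_params) {
  n <- length(egg_rows)
  if (!n) return(NULL)
  e <- eggs[egg_rows, , drop = FALSE]
  recs <- vector("list", length(group_params))
  for (g in seq_along(group_params)) {
    gi <- which(e$group == g)
    if (!length(gi)) next
    p <- group_params[[g]]
    ng <- length(gi)
    rec <- .fast_df(list(
      id = rep.int(NA_integer_, ng),
      sex = e$sex[gi],
      age = rep.int(0L, ng),
      lifespan = sample_truncated_weibull(ng, p$weibull_shape, p$weibull_scale,
                                          1L, p$lifespan_max),
      eggs = sample_truncated_poisson(ng, p$pois_rate, 1L, p$eggs_max),
      trait_lay_success = e$lay_success[gi],
      trait_mimic_color = e$mimic_color[gi],
      trait_mimic_shape = e$mimic_shape[gi],
      trait_mimic_vocal = e$mimic_vocal[gi],
      trait_fertility = e$fertility[gi]
    ))
    rec$cur_lay_success <- rec$trait_lay_success
    rec$group <- rep.int(g, ng)
    rec$pref <- ifelse(rec$sex == "F", e$pref[gi], NA_integer_)
    recs[[g]] <- rec
  }
  recs <- recs[!vapply(recs, is.null, logical(1))]
  if (!length(recs)) return(NULL)
  do.call(rbind, recs)
}

#' Initialize the simulation state from a configuration
#'
#' @param config A [bp_config()] configuration.
#' @return A state list with `year`, the cuckoo population (all groups in one
#'   table with a `group` column) and one host population table per species.
#' @export
init_state <- function(config) {
  stopifnot(inherits(config, "bp_config"))
  cks <- lapply(seq_along(config$cuckoos), function(g) {
    init_population(config$cuckoos[[g]], group = g)
  })
  cuckoos <- do.call(rbind, cks)
  hosts <- lapply(seq_len(config$n_host_species), function(s) init_population(config$host))
  list(year = 0L, cuckoos = cuckoos, hosts = hosts)
}

#' Advance the simulation by one year
#'
#' Executes one full annual cycle and returns the updated state plus the
#' year's census record (populations, nest counts, parasitized nests,
#' parasitism ratio).
#'
#' @param state State list from [init_state()] or a previous `run_year()`.
#' @param config The [bp_config()] configuration.
#' @return List with `state` (next year's state) and `record` (one-row data
#'   frame: year, cuckoo census per group and total, host census per species,
#'   nests, parasitized nests, PR).
#' @export
run_year <- function(state, config) {
  hostp <- config$host
  nhs <- config$n_host_species
  hosts <- state$hosts
  cuckoos <- state$cuckoos
  year <- state$year + 1L
  reg <- vapply(hosts, function(h) regulation_coefficient(nrow(h), hostp$capacity),
                numeric(1))

  pairs_l <- lapply(hosts, make_pairs)
  nests_l <- lapply(seq_len(nhs), function(s) {
    .build_nests(hosts[[s]], pairs_l[[s]]$pairs)
  })

  eggs <- generate_cuckoo_eggs(cuckoos, config$cuckoos)

  leftover <- integer(0)
  laid_mothers <- integer(0)
  if (nrow(eggs)) {
    pass1 <- run_parasitism(eggs, seq_len(nrow(eggs)), nests_l, cuckoos,
                            backup = config$backup)
    nests_l <- pass1$nests_list
    leftover <- pass1$leftover
    laid_mothers <- pass1$laid_mothers
  }

  res_l <- lapply(seq_len(nhs), function(s) resolve_nests(nests_l[[s]], eggs, reg[s]))

  # vocal-rejection abandonments re-nest once; re-nests can only be
  # parasitized by eggs still unlaid from the first pass
  renests_l <- lapply(seq_len(nhs), function(s) {
    idx <- which(res_l[[s]]$abandoned & nests_l[[s]]$renest < config$renest_max)
    .build_nests(hosts[[s]], nests_l[[s]][idx, c("f", "m"), drop = FALSE], renest = 1L)
  })
  any_renest <- sum(vapply(renests_l, nrow, integer(1))) > 0L
  res2_l <- NULL
  if (any_renest) {
    if (length(leftover)) {
      pass2 <- run_parasitism(eggs, leftover, renests_l, cuckoos,
                              backup = config$backup)
      renests_l <- pass2$nests_list
      laid_mothers <- unique(c(laid_mothers, pass2$laid_mothers))
    }
    res2_l <- lapply(seq_len(nhs), function(s) {
      resolve_nests(renests_l[[s]], eggs, reg[s])
    })
  }

  # --- recruits
  host_rec <- vector("list", nhs)
  cuckoo_egg_rows <- integer(0)
  for (s in seq_len(nhs)) {
    rec1 <- .host_recruits(hosts[[s]], nests_l[[s]], res_l[[s]]$host_fledge, hostp)
    rec2 <- if (!is.null(res2_l)) {
      .host_recruits(hosts[[s]], renests_l[[s]], res2_l[[s]]$host_fledge, hostp)
    }
    rec_s <- if (is.null(rec1)) rec2 else if (is.null(rec2)) rec1 else rbind(rec1, rec2)
    host_rec[s] <- list(rec_s)
    cuckoo_egg_rows <- c(cuckoo_egg_rows, res_l[[s]]$cuckoo_fledged_egg,
                         if (!is.null(res2_l)) res2_l[[s]]$cuckoo_fledged_egg)
  }
  cuckoo_rec <- .cuckoo_recruits(eggs, cuckoo_egg_rows, config$cuckoos)

  # --- reinforcement (once per trigger per individual, after all nests resolve)
  if (length(laid_mothers)) {
    g <- cuckoos$group[laid_mothers]
    delta <- vapply(config$cuckoos, function(p) p$reinforcement[["lay_success"]],
                    numeric(1))[g]
    cuckoos$cur_lay_success[laid_mothers] <-
      apply_reinforcement(cuckoos$cur_lay_success[laid_mothers], delta)
  }
  rf <- hostp$reinforcement
  for (s in seq_len(nhs)) {
    all_nests <- nests_l[[s]]
    states <- list(res_l[[s]])
    if (!is.null(res2_l)) {
      all_nests <- rbind(all_nests, renests_l[[s]])
      states <- c(states, list(res2_l[[s]]))
    }
    attempted <- all_nests$attempted
    deceived <- unlist(lapply(states, `[[`, "deceived"))
    fledged_own <- unlist(lapply(states, `[[`, "host_fledge")) > 0L
    members <- function(flag) unique(c(all_nests$f[flag], all_nests$m[flag]))
    h <- hosts[[s]]
    i <- members(attempted)
    if (length(i)) h$cur_nest_guard[i] <- apply_reinforcement(h$cur_nest_guard[i], rf[["nest_guard"]])
    i <- members(deceived)
    if (length(i)) {
      h$cur_detect_color[i] <- apply_reinforcement(h$cur_detect_color[i], rf[["detect_color"]])
      h$cur_detect_shape[i] <- apply_reinforcement(h$cur_detect_shape[i], rf[["detect_shape"]])
      h$cur_detect_vocal[i] <- apply_reinforcement(h$cur_detect_vocal[i], rf[["detect_vocal"]])
    }
    i <- members(fledged_own)
    if (length(i)) h$cur_rearing[i] <- apply_reinforcement(h$cur_rearing[i], rf[["rearing"]])
    hosts[[s]] <- h
  }

  # --- cohort turnover: age, remove dead, recruit fledglings at age 0
  age_out <- function(df) {
    df$age <- df$age + 1L
    keep <- df$age < df$lifespan
    if (all(keep)) df else .subset_rows(df, keep)
  }
  cuckoos <- age_out(cuckoos)
  if (!is.null(cuckoo_rec)) cuckoos <- rbind(cuckoos, cuckoo_rec)
  for (s in seq_len(nhs)) {
    hosts[[s]] <- age_out(hosts[[s]])
    if (!is.null(host_rec[[s]])) hosts[[s]] <- rbind(hosts[[s]], host_rec[[s]])
  }

  n_nests <- sum(vapply(nests_l, nrow, integer(1))) +
    if (any_renest) sum(vapply(renests_l, nrow, integer(1))) else 0L
  n_par <- sum(vapply(nests_l, function(ns) sum(ns$par > 0L), integer(1))) +
    if (any_renest) sum(vapply(renests_l, function(ns) sum(ns$par > 0L), integer(1))) else 0L

  n_groups <- length(config$cuckoos)
  by_group <- vapply(seq_len(n_groups), function(g) sum(cuckoos$group == g), integer(1))
  record <- data.frame(year = year, cuckoo_n = nrow(cuckoos))
  if (n_groups > 1L) {
    for (g in seq_len(n_groups)) record[[paste0("cuckoo_n_g", g)]] <- by_group[g]
  }
  for (s in seq_len(nhs)) record[[paste0("host_n_", s)]] <- nrow(hosts[[s]])
  record$nests <- n_nests
  record$parasitized_nests <- n_par
  record$pr <- parasitism_ratio(n_par, n_nests)

  list(state = list(year = year, cuckoos = cuckoos, hosts = hosts),
       record = record)
}

#' Run a full multi-year simulation
#'
#' Iterates [run_year()] from a freshly initialized state, recording the
#' per-year census. The run halts early when both the parasite and every host
#' species are extinct (`halt = "both"`, the default) or as soon as the
#' parasite is extinct (`halt = "parasite"`, useful for parasite-focused
#' ensembles since all reported metrics are then zero).
#'
#' @param config A [bp_config()] configuration.
#' @param years Number of years to simulate, `>= 1`.
#' @param seed Optional integer seed set before initialization.
#' @param halt Early-termination rule: `"both"`, `"parasite"` or `"none"`.
#' @return A data frame of class `bp_sim`, one row per simulated year
#'   (including year 0), with columns `year`, `cuckoo_n` (and per-group counts
#'   when several cuckoo groups run jointly), `host_n_<s>`, `nests`,
#'   `parasitized_nests`, `pr` and `rp` (cuckoo relative population, percent).
#' @export
run_simulation <- function(config, years = 300L, seed = NULL,
                           halt = c("both", "parasite", "none")) {
  halt <- match.arg(halt)
  stopifnot(inherits(config, "bp_config"))
  years <- as.integer(years)
  if (is.na(years) || years < 1L) .invalid_config("years must be >= 1")
  if (!is.null(seed)) set.seed(as.integer(seed))
  state <- init_state(config)
  n0_cuckoo <- nrow(state$cuckoos)
  records <- vector("list", years + 1L)
  rec0 <- data.frame(year = 0L, cuckoo_n = n0_cuckoo)
  if (length(config$cuckoos) > 1L) {
    for (g in seq_along(config$cuckoos)) {
      rec0[[paste0("cuckoo_n_g", g)]] <- sum(state$cuckoos$group == g)
    }
  }
  for (s in seq_len(config$n_host_species)) {
    rec0[[paste0("host_n_", s)]] <- nrow(state$hosts[[s]])
  }
  rec0$nests <- NA_integer_
  rec0$parasitized_nests <- NA_integer_
  rec0$pr <- NA_real_
  records[[1L]] <- rec0
  used <- 1L
  for (t in seq_len(years)) {
    step <- run_year(state, config)
    state <- step$state
    used <- used + 1L
    records[[used]] <- step$record
    cuckoo_gone <- nrow(state$cuckoos) == 0L
    hosts_gone <- all(vapply(state$hosts, nrow, integer(1)) == 0L)
    if (halt == "both" && cuckoo_gone && hosts_gone) break
    if (halt == "parasite" && cuckoo_gone && n0_cuckoo > 0L) break
  }
  out <- do.call(rbind, records[seq_len(used)])
  out$rp <- if (n0_cuckoo > 0L) relative_population(out$cuckoo_n, n0_cuckoo) else NA_real_
  attr(out, "config") <- config
  attr(out, "years_requested") <- years
  attr(out, "seed") <- seed
  class(out) <- c("bp_sim", class(out))
  out
}
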