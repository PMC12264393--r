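# Annual-cycle mechanics: net probabilities, detection, regulation,
# reinforcement, nest resolution, parasitism targeting, determinism.

# Hand-built nest/egg tables for resolve_nests and run_parasitism.
nest_rows <- function(n, clutch = 5L, guard = 0.30, dcol = 0.40, dshp = 0.40,
                      dvoc = 0.30, fert = 0.75, rear = 0.75, par = 0L) {
  data.frame(f = seq_len(n), m = seq_len(n), clutch = rep.int(as.integer(clutch), n),
             guard = rep_len(guard, n), dcol = rep_len(dcol, n),
             dshp = rep_len(dshp, n), dvoc = rep_len(dvoc, n),
             fert = rep_len(fert, n), rear = rep_len(rear, n),
             renest = rep.int(0L, n),
             par = rep.int(as.integer(par), n), attempted = rep.int(FALSE, n))
}

egg_rows <- function(n, mc = 0.15, ms = 0.15, mv = 0.20, mfert = 0.75,
                     mother = 1L, pref = 1L) {
  data.frame(mother = rep.int(as.integer(mother), n), group = 1L,
             pref = rep.int(as.integer(pref), n),
             sex = rep("F", n), mimic_color = mc, mimic_shape = ms,
             mimic_vocal = mv, lay_success = 0.65, fertility = 0.75,
             mother_fertility = mfert, stringsAsFactors = FALSE)
}

test_that("clipped difference floors at zero", {
  expect_equal(clipped_difference(0.40, 0.15), 0.25)
  expect_equal(clipped_difference(0.15, 0.40), 0)
  for (x in c(0, 0.3, 1)) expect_equal(clipped_difference(x, x), 0)
})

test_that("egg detection combines colour and shape channels", {
  expect_equal(egg_detection_probability(0.40, 0.15, 0.40, 0.15), 0.4375)
  expect_equal(egg_detection_probability(0.40, 0.40, 0.40, 0.10), 0.30)
  expect_equal(egg_detection_probability(0.40, 0.40, 0.40, 0.40), 0)
  expect_equal(egg_detection_probability(0.40, 0.60, 0.40, 0.55), 0)
})

test_that("regulation coefficient is the linear logistic factor", {
  expect_equal(regulation_coefficient(0, 100), 1)
  expect_equal(regulation_coefficient(50, 100), 0.5)
  expect_equal(regulation_coefficient(100, 100), 0)
  expect_equal(regulation_coefficient(150, 100), 0)
  expect_error(regulation_coefficient(10, 0), class = "bp_invalid_config")
})

test_that("reinforcement adds the increment and caps at one", {
  expect_equal(apply_reinforcement(0.40, 0.004), 0.404)
  expect_equal(apply_reinforcement(0.999, 0.004), 1)
  p <- 0.3
  for (i in 1:1000) p <- apply_reinforcement(p, 0.01)
  expect_equal(p, 1)
})

test_that("non-parasitized nests fledge binomially with the pair product", {
  set.seed(31)
  n <- 1e4
  res <- resolve_nests(nest_rows(n, clutch = 5L, fert = 0.75, rear = 0.75),
                       egg_rows(0), reg = 1)
  expect_true(all(res$state == "nonparasitized"))
  m <- mean(res$host_fledge)
  se <- stats::sd(res$host_fledge) / sqrt(n)
  expect_lt(abs(m - 5 * 0.5625), 3 * se)
})

test_that("certain vocal detection abandons the nest with zero fledglings", {
  set.seed(32)
  nests <- nest_rows(50, dcol = 0, dshp = 0, dvoc = 1)
  nests$par <- 1:50
  eggs <- egg_rows(50, mc = 0.5, ms = 0.5, mv = 0, mfert = 1)
  res <- resolve_nests(nests, eggs, reg = 1)
  expect_true(all(res$state == "parasitized_hatched"))
  expect_true(all(res$abandoned))
  expect_true(all(res$host_fledge == 0))
  expect_length(res$cuckoo_fledged_egg, 0)
})

test_that("an unrejected cuckoo chick kills host nestlings and is reared alone", {
  set.seed(33)
  nests <- nest_rows(200, dcol = 0, dshp = 0, dvoc = 0, rear = 1)
  nests$par <- 1:200
  eggs <- egg_rows(200, mv = 0.5, mfert = 1)
  res <- resolve_nests(nests, eggs, reg = 1)
  expect_true(all(res$state == "parasitized_hatched"))
  expect_true(all(res$host_fledge == 0))
  expect_true(all(res$deceived))
  expect_lte(length(res$cuckoo_fledged_egg), 200)
  expect_gt(length(res$cuckoo_fledged_egg), 0)
})

test_that("every resolved nest lands in exactly one of the four states", {
  set.seed(34)
  nests <- nest_rows(500)
  nests$par[sample.int(500, 250)] <- seq_len(250)
  eggs <- egg_rows(250)
  res <- resolve_nests(nests, eggs, reg = 0.8)
  expect_false(anyNA(res$state))
  expect_true(all(res$state[nests$par == 0] == "nonparasitized"))
  expect_true(all(res$state[nests$par > 0] != "nonparasitized"))
  expect_true(all(res$abandoned | !res$abandoned))
  # abandonment only after a hatched parasite
  expect_true(all(res$state[res$abandoned] == "parasitized_hatched"))
  expect_true(all(res$state[res$deceived] == "parasitized_hatched"))
})

test_that("parasitism targets the preferred species and respects back-up", {
  set.seed(35)
  cuckoos <- init_population(tiny_cuckoo(4))
  cuckoos$sex <- c("F", "F", "M", "M")
  cuckoos$cur_lay_success <- 1
  nests1 <- nest_rows(3, guard = 0)
  nests2 <- nest_rows(3, guard = 0)
  # preferred species has room -> all eggs land there
  eggs <- egg_rows(3, mother = 1L, pref = 1L)
  out <- run_parasitism(eggs, 1:3, list(nests1, nests2), cuckoos, backup = TRUE)
  expect_equal(sum(out$nests_list[[1]]$par > 0), 3)
  expect_equal(sum(out$nests_list[[2]]$par > 0), 0)
  # preferred full: backup redirects, disabled backup leaves eggs unlaid
  full1 <- nest_rows(2, guard = 0); full1$par <- 1:2
  eggs2 <- egg_rows(2, mother = 2L, pref = 1L)
  with_bu <- run_parasitism(eggs2, 1:2, list(full1, nest_rows(4, guard = 0)),
                            cuckoos, backup = TRUE)
  expect_equal(sum(with_bu$nests_list[[2]]$par > 0), 2)
  no_bu <- run_parasitism(eggs2, 1:2, list(full1, nest_rows(4, guard = 0)),
                          cuckoos, backup = FALSE)
  expect_equal(sum(no_bu$nests_list[[2]]$par > 0), 0)
  expect_equal(no_bu$leftover, 1:2)
})

test_that("laying never succeeds when guarding matches laying skill", {
  set.seed(36)
  cuckoos <- init_population(tiny_cuckoo(2))
  cuckoos$sex <- c("F", "M")
  cuckoos$cur_lay_success <- 0.5
  nests <- nest_rows(10, guard = 0.5)
  out <- run_parasitism(egg_rows(20, mother = 1L), 1:20, list(nests, nest_rows(0)),
                        cuckoos, backup = TRUE)
  expect_equal(sum(out$nests_list[[1]]$par > 0), 0)
  expect_true(any(out$nests_list[[1]]$attempted)) # attempts still experienced
})

test_that("a nest accepts at most one parasite egg", {
  set.seed(37)
  cuckoos <- init_population(tiny_cuckoo(10))
  cuckoos$sex <- rep(c("F", "M"), 5)
  cuckoos$cur_lay_success <- 1
  nests <- nest_rows(5, guard = 0)
  eggs <- egg_rows(40, mother = 1L)
  out <- run_parasitism(eggs, 1:40, list(nests, nest_rows(0)), cuckoos)
  par <- out$nests_list[[1]]$par
  expect_equal(sum(par > 0), 5)
  expect_false(any(duplicated(par[par > 0])))
})

test_that("reinforcement is not heritable: eggs inherit pre-reinforcement traits", {
  set.seed(38)
  p <- tiny_cuckoo(2, prob_sds = c(lay_success = 0, mimic_color = 0,
                                   mimic_shape = 0, mimic_vocal = 0, fertility = 0))
  pop <- init_population(p)
  pop$sex <- c("F", "M")
  pop$trait_lay_success <- c(0.60, 0.70)
  pop$cur_lay_success <- c(0.90, 0.95) # heavily reinforced parents
  pop$trait_mimic_color <- c(0.15, 0.15)
  eggs <- generate_cuckoo_eggs(pop, list(p))
  expect_equal(eggs$lay_success, rep(0.65, nrow(eggs))) # mid-parent heritable value
  expect_equal(eggs$mimic_color, rep(0.15, nrow(eggs))) # maternal heritable value
})

test_that("maternal traits ignore the sire; egg counts honour capacity", {
  set.seed(39)
  p <- tiny_cuckoo(4, prob_sds = c(lay_success = 0.001, mimic_color = 0,
                                   mimic_shape = 0, mimic_vocal = 0, fertility = 0.001))
  pop <- init_population(p)
  pop$sex <- c("F", "M", "M", "M")
  pop$eggs[1] <- 4L
  pop$trait_mimic_color <- c(0.15, 0.9, 0.9, 0.9)
  eggs <- generate_cuckoo_eggs(pop, list(p))
  expect_equal(nrow(eggs), 4)
  expect_true(all(eggs$mimic_color == 0.15))
  expect_true(all(eggs$mother == 1L))
  # no males -> no eggs
  pop2 <- pop[pop$sex == "F", , drop = FALSE]
  expect_equal(nrow(generate_cuckoo_eggs(pop2, list(p))), 0)
})

test_that("one simulated year preserves core state invariants", {
  set.seed(40)
  cfg <- tiny_config(n_cuckoo = 30, n_host = 60)
  st <- init_state(cfg)
  for (i in 1:15) {
    step <- run_year(st, cfg)
    st <- step$state
    rec <- step$record
    expect_lte(rec$parasitized_nests, rec$nests)
    expect_true(rec$pr >= 0 && rec$pr <= 1)
    if (nrow(st$cuckoos)) {
      expect_true(all(st$cuckoos$age < st$cuckoos$lifespan))
      expect_true(all(st$cuckoos$cur_lay_success >= 0 & st$cuckoos$cur_lay_success <= 1))
    }
    for (h in st$hosts) {
      if (!nrow(h)) next
      expect_true(all(h$age < h$lifespan))
      cur <- h[grep("^cur_", names(h))]
      expect_true(all(cur >= 0 & cur <= 1))
    }
  }
})

test_that("a host-only world has no parasitism and stays near capacity", {
  set.seed(41)
  cfg <- tiny_config(n_cuckoo = 0, n_host = 60)
  sim <- run_simulation(cfg, years = 60, halt = "both")
  expect_true(all(sim$pr[-1] == 0))
  late <- sim[sim$year > 20, ]
  expect_true(all(late$host_n_1 > 0))
  expect_true(all(late$host_n_1 < 1.3 * 120))
})

test_that("simulations are bit-identical under a fixed seed", {
  cfg <- tiny_config()
  a <- run_simulation(cfg, years = 12, seed = 7)
  b <- run_simulation(cfg, years = 12, seed = 7)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_error(run_simulation(cfg, years = 0), class = "bp_invalid_config")
})

test_that("raising host capacity does not reduce median host population", {
  set.seed(43)
  med_host <- function(K) {
    finals <- vapply(1:8, function(r) {
      cfg <- bp_config(tiny_cuckoo(20), tiny_host(50, capacity = K))
      sim <- run_simulation(cfg, years = 50, seed = 1000 + r, halt = "none")
      k <- nrow(sim)
      sim$host_n_1[k] + sim$host_n_2[k]
    }, numeric(1))
    stats::median(finals)
  }
  expect_gte(med_host(300L), med_host(150L))
})
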