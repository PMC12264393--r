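# Scenario plumbing: HLF scaling, ensembles, RR mapping, sweeps.

test_that("scenario specs validate their fields", {
  s <- scenario_spec(hlf_level = 0.75, years = 10, n_replicates = 2)
  expect_s3_class(s, "bp_scenario")
  expect_error(scenario_spec(hlf_level = 0), class = "bp_invalid_config")
  expect_error(scenario_spec(hlf_level = 1.2), class = "bp_invalid_config")
  expect_error(scenario_spec(years = 0), class = "bp_invalid_config")
  expect_error(scenario_spec(n_replicates = 0), class = "bp_invalid_config")
})

test_that("HLF scales capacity and initial populations proportionally", {
  cfg <- make_fixture("A")
  mod <- apply_hlf(cfg, 0.75)
  expect_equal(mod$host$capacity, round(cfg$host$capacity * 0.75))
  expect_equal(mod$host$n_initial, round(cfg$host$n_initial * 0.75))
  expect_equal(mod$cuckoos[[1]]$n_initial, round(cfg$cuckoos[[1]]$n_initial * 0.75))
  sev <- apply_hlf(cfg, 0.5)
  expect_equal(sev$host$capacity, round(cfg$host$capacity * 0.5))
  # untouched parameters and the level-1 identity
  expect_equal(mod$host$prob_means, cfg$host$prob_means)
  expect_identical(apply_hlf(cfg, 1), cfg)
  expect_error(apply_hlf(cfg, 0), class = "bp_invalid_config")
})

test_that("a one-replicate ensemble summary equals its single series", {
  cfg <- tiny_config(n_cuckoo = 16, n_host = 30)
  ens <- run_ensemble(cfg, scenario_spec(years = 8, n_replicates = 1, master_seed = 3))
  expect_equal(ens$summary$rp_median, as.numeric(ens$rp[, 1]))
  expect_equal(ens$summary$rp_mean, as.numeric(ens$rp[, 1]))
  expect_equal(ens$rp_final, unname(ens$rp[9, ]))
})

test_that("the same master seed reproduces an ensemble exactly", {
  cfg <- tiny_config(n_cuckoo = 16, n_host = 30)
  sc <- scenario_spec(years = 6, n_replicates = 3, master_seed = 11)
  a <- run_ensemble(cfg, sc)
  b <- run_ensemble(cfg, sc)
  expect_identical(a$rp, b$rp)
  expect_identical(a$pr, b$pr)
  expect_identical(a$survival_periods, b$survival_periods)
})

test_that("extinct replicates are padded with zeros and censored survival", {
  # a parasite that can never lay goes extinct within its lifespan
  ck <- tiny_cuckoo(12, prob_means = c(lay_success = 0.01, mimic_color = 0.15,
                                       mimic_shape = 0.15, mimic_vocal = 0.2,
                                       fertility = 0.75))
  cfg <- bp_config(ck, tiny_host(30))
  ens <- run_ensemble(cfg, scenario_spec(years = 15, n_replicates = 3, master_seed = 2))
  expect_true(all(ens$survival_periods <= 11))
  expect_true(all(ens$rp_final == 0))
  expect_true(all(ens$rp[16, ] == 0))
})

test_that("rejection rates map to mimicry as host level minus RR", {
  expect_equal(rr_to_mimicry(0.25), 0.15)
  expect_equal(rr_to_mimicry(0.30), 0.10)
  expect_equal(rr_to_mimicry(0), 0.40)
  expect_error(rr_to_mimicry(0.5), class = "bp_invalid_config")
  expect_error(rr_to_mimicry(-0.1), class = "bp_invalid_config")
})

test_that("the default RR grid has 81 cells and sweeps record summaries", {
  g <- expand.grid(color_rr = seq(0, 0.40, by = 0.05),
                   shape_rr = seq(0, 0.40, by = 0.05))
  expect_equal(nrow(g), 81)
  cfg <- tiny_config(n_cuckoo = 14, n_host = 30)
  sw <- rr_grid_sweep(cfg, scenario_spec(years = 5, n_replicates = 2, master_seed = 4),
                      color_rr_values = c(0.20, 0.25),
                      shape_rr_values = c(0.20, 0.25))
  expect_equal(nrow(sw), 4)
  expect_true(all(c("color_rr", "shape_rr", "median_survival", "median_rp_final")
                  %in% names(sw)))
  expect_true(all(sw$median_survival <= 5))
  expect_error(rr_grid_sweep(cfg, color_rr_values = c(0.3, 0.1)),
               class = "bp_invalid_config")
})

test_that("parameter overrides rebuild derived quantities consistently", {
  cfg <- make_fixture("A")
  # lifespan hazard is preserved when only the maximum changes
  mod <- set_param(cfg, "cuckoo_lifespan_max", 12L)
  expect_equal(mod$cuckoos[[1]]$weibull_scale, cfg$cuckoos[[1]]$weibull_scale)
  expect_gt(mod$cuckoos[[1]]$lifespan_mean, cfg$cuckoos[[1]]$lifespan_mean)
  # probability overrides refresh the defaulted sd
  mod2 <- set_param(cfg, "cuckoo_fertility", 0.8)
  expect_equal(mod2$cuckoos[[1]]$prob_means[["fertility"]], 0.8)
  expect_equal(mod2$cuckoos[[1]]$prob_sds[["fertility"]], 0.008)
  # C-H ratio rescales the cuckoo side only
  mod3 <- set_param(cfg, "ch_ratio", 1 / 3)
  host_total <- cfg$host$n_initial * cfg$n_host_species
  expect_equal(mod3$cuckoos[[1]]$n_initial, round(host_total / 3))
  expect_equal(mod3$host$n_initial, cfg$host$n_initial)
  expect_error(set_param(cfg, "nonsense", 1), class = "bp_invalid_config")
})

test_that("sensitivity sweeps validate inputs and produce one row per value", {
  cfg <- tiny_config(n_cuckoo = 14, n_host = 30)
  sc <- scenario_spec(years = 5, n_replicates = 2, master_seed = 9)
  out <- sensitivity_sweep(cfg, "cuckoo_lifespan_max", c(8, 10, 12), sc)
  expect_equal(nrow(out), 3)
  expect_equal(out$value, c(8, 10, 12))
  expect_error(sensitivity_sweep(cfg, "bad_param", 1:2, sc),
               class = "bp_invalid_config")
  expect_error(sensitivity_sweep(cfg, "ch_ratio", numeric(0), sc),
               class = "bp_invalid_config")
})

test_that("scenario backup flag and overrides reach the executed config", {
  cfg <- tiny_config(n_cuckoo = 14, n_host = 30)
  ens <- run_ensemble(cfg, scenario_spec(years = 3, n_replicates = 1, backup = FALSE,
                                         overrides = list(host_rearing = 0.7)))
  expect_false(ens$config$backup)
  expect_equal(ens$config$host$prob_means[["rearing"]], 0.7)
})

test_that("joint mode runs several cuckoo groups against a shared host pool", {
  set.seed(50)
  groups <- list(tiny_cuckoo(10), tiny_cuckoo(10, prob_means = c(
    lay_success = 0.65, mimic_color = 0.25, mimic_shape = 0.25,
    mimic_vocal = 0.2, fertility = 0.75)))
  cfg <- bp_config(groups, tiny_host(40))
  sim <- run_simulation(cfg, years = 6, seed = 31)
  expect_true(all(c("cuckoo_n_g1", "cuckoo_n_g2") %in% names(sim)))
  expect_equal(sim$cuckoo_n, sim$cuckoo_n_g1 + sim$cuckoo_n_g2)
})
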