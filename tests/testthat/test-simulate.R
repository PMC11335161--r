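test_that("cohort has exactly the requested size and valid fields", {
  co <- simulate_cohort(compact_sim_config(4042, seed = 2))
  expect_equal(nrow(co), 4042)
  expect_true(all(co$time > 0))
  expect_true(all(co$event %in% 0:1))
  expect_true(all(co$treatment %in% 0:1))
  expect_false(anyNA(co))
})

test_that("identical config and seed reproduce the cohort exactly", {
  c1 <- simulate_cohort(compact_sim_config(300, seed = 9))
  c2 <- simulate_cohort(compact_sim_config(300, seed = 9))
  expect_identical(c1, c2)
  c3 <- simulate_cohort(compact_sim_config(300, seed = 10))
  expect_false(identical(c1$time, c3$time))
})

test_that("zero treatment effect yields zero true ITE everywhere", {
  co <- simulate_cohort(compact_sim_config(200, seed = 4, effect = "null"))
  expect_equal(co$true_ite_months, rep(0, 200))
  expect_equal(co$true_log_hr, rep(0, 200))
})

test_that("randomized assignment balances covariates at large n", {
  cfg <- compact_sim_config(20000, seed = 6)
  cfg$propensity_coefficients <- list()
  cfg$region_sd <- 0
  co <- simulate_cohort(cfg)
  x <- cohort_design(co)
  balance <- smd(x, co$treatment)
  expect_lt(max(abs(balance)), 0.05)
})

test_that("covariate marginals and censoring match the configuration at large n", {
  cfg <- compact_sim_config(20000, seed = 12, censoring = 0.5)
  co <- simulate_cohort(cfg)
  expect_lt(abs(mean(co$event == 0) - 0.5), 0.03)
  expect_lt(abs(mean(co$sex == "male") - 0.55), 0.02)
  hist_freq <- table(co$histology) / nrow(co)
  expect_lt(max(abs(hist_freq - c(0.37, 0.18, 0.45))), 0.02)
})

test_that("observed Kaplan-Meier medians match the closed-form truth", {
  # uncensored, by (arm x responsiveness stratum): exponential medians
  cfg <- compact_sim_config(20000, seed = 8, censoring = 0, effect = "hetero")
  co <- simulate_cohort(cfg)
  grp <- cohort_group_labels(co)
  for (arm in 0:1) {
    for (g in c("A", "B")) {
      idx <- co$treatment == arm & grp == g
      med_obs <- unname(stats::median(co$time[idx]))
      lam <- cfg$baseline_hazard_scale *
        exp(bslnet:::coef_linear_predictor(co[idx, ],
                                           cfg$prognostic_coefficients,
                                           cfg$covariate_spec) +
              arm * co$true_log_hr[idx])
      # closed-form median of the stratum's exponential mixture
      med_true <- stats::uniroot(function(t) mean(exp(-lam * t)) - 0.5,
                                 c(1e-3, 1e5))$root
      expect_lt(abs(med_obs - med_true) / med_true, 0.05)
    }
  }
})

test_that("true group labels follow the under-40 overlapping/midline rule", {
  expect_equal(true_group_label(list(age = 35, location = "overlapping",
                                     extension = "confined")), "A")
  expect_equal(true_group_label(list(age = 39, location = "frontal",
                                     extension = "midline")), "A")
  expect_equal(true_group_label(list(age = 55, location = "frontal",
                                     extension = "confined")), "B")
  expect_equal(true_group_label(list(age = 40, location = "overlapping",
                                     extension = "midline")), "B")  # strict <
  expect_error(true_group_label(list(age = 30, location = "frontal")),
               "extension")
})

test_that("invalid configurations are rejected with clear messages", {
  expect_error(simulation_config(1), "n_patients")
  expect_error(simulation_config(100, censoring_rate_target = 1),
               "censoring_rate_target")
  cfg_bad <- compact_sim_config(100)
  expect_error(
    simulation_config(100, covariate_spec = compact_covariate_spec(),
                      effect_modifiers = list(rules = list(
                        list(expr = "nonexistent > 1", log_hr = -1)),
                        default_log_hr = 0)),
    "undeclared")
})

test_that("a degenerate propensity names the empty arm", {
  cfg <- compact_sim_config(50, seed = 3)
  cfg$treatment_prevalence <- 0.9999999
  expect_error(simulate_cohort(cfg), "arm")
})

test_that("cohort CSV round-trips through write/read", {
  co <- simulate_cohort(compact_sim_config(60, seed = 5))
  path <- tempfile(fileext = ".csv")
  write_cohort(co, path)
  co2 <- read_cohort(path)
  expect_equal(nrow(co2), 60)
  expect_equal(co2$time, co$time, tolerance = 1e-12)
  expect_equal(as.character(co2$histology), as.character(co$histology))
})

test_that("simulation config YAML round-trips", {
  cfg <- compact_sim_config(120, seed = 77)
  path <- tempfile(fileext = ".yaml")
  write_simulation_config(cfg, path)
  cfg2 <- read_simulation_config(path)
  expect_identical(simulate_cohort(cfg), simulate_cohort(cfg2))
})
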