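test_that("time at risk recovers the exponential median on a monthly grid", {
  lam <- log(2) / 24
  curve <- list(time = 0:120, surv = exp(-lam * (0:120)))
  tar <- time_at_risk(curve, horizon = 120)
  expect_true(tar$median_reached)
  expect_lte(abs(tar$tar - 24), 1)
})

test_that("time at risk honors the definition and the horizon fallback", {
  curve <- list(time = c(0, 5, 10, 15), surv = c(1, 0.8, 0.5, 0.2))
  expect_equal(time_at_risk(curve, 100)$tar, 10)   # first time S <= 0.5
  flat <- list(time = c(0, 50), surv = c(1, 1))
  tr <- time_at_risk(flat, 60)
  expect_equal(tr$tar, 60)
  expect_false(tr$median_reached)
  expect_error(time_at_risk(list(time = numeric(0), surv = numeric(0)), 10),
               "empty")
})

test_that("predicted curves obey the survival contract", {
  bh <- make_basehaz(c(5, 10, 20), c(0.2, 0.5, 1.2))
  m <- zero_model(p = 3, basehaz0 = bh, basehaz1 = bh)
  cu <- predict_survival(m, c(0.1, -0.2, 0.3), arm = 0)
  expect_equal(cu$surv[1], 1)
  expect_true(all(diff(cu$surv) <= 0))
  expect_true(all(cu$surv >= 0 & cu$surv <= 1))
  # zero scores: S(t) = exp(-H0(t))
  expect_equal(cu$surv, exp(-c(0, bh$hazard)))
})

test_that("identical heads give zero ITE and the tie resolves to RT", {
  bh <- make_basehaz(c(6, 12, 30), c(0.3, 0.8, 1.5))
  m <- zero_model(p = 2, basehaz0 = bh, basehaz1 = bh)
  it <- compute_ite(m, matrix(rnorm(6), 3, 2), horizon = 100)
  expect_equal(it$ite, rep(0, 3))
  expect_equal(it$recommendation, rep("RT", 3))
})

test_that("constructed medians 20 vs 30 produce ITE +10 and a CRT call", {
  m <- zero_model(p = 2,
                  basehaz0 = make_basehaz(20, 0.7),   # S(20) < 0.5
                  basehaz1 = make_basehaz(30, 0.7))
  it <- compute_ite(m, matrix(0, 1, 2), horizon = 100)
  expect_equal(it$tar_rt, 20)
  expect_equal(it$tar_crt, 30)
  expect_equal(it$ite, 10)
  expect_equal(it$recommendation, "CRT")
})

test_that("compute_ite agrees with per-patient curve evaluation", {
  dat <- linear_cox_data(300, seed = 3)
  cfg <- tiny_bsl_config(max_iterations = 60, balance_alpha = 0)
  m <- bsl_fit(dat$x, dat$time, dat$event, dat$treatment, cfg)
  it <- compute_ite(m, dat$x[1:20, ], horizon = m$horizon)
  for (i in c(1, 7, 20)) {
    t0 <- time_at_risk(predict_survival(m, dat$x[i, ], 0), m$horizon)
    t1 <- time_at_risk(predict_survival(m, dat$x[i, ], 1), m$horizon)
    expect_equal(it$tar_rt[i], t0$tar)
    expect_equal(it$tar_crt[i], t1$tar)
    expect_equal(it$ite[i], t1$tar - t0$tar)
  }
})

test_that("raising a patient's risk score never raises that arm's TaR", {
  bh <- make_basehaz(c(4, 9, 14, 33), c(0.1, 0.4, 0.8, 1.6))
  m <- zero_model(p = 2, basehaz0 = bh, basehaz1 = bh)
  # score is monotone in the skip weight times input; emulate via baselines
  tars <- vapply(c(-1, 0, 1, 2), function(s) {
    cu <- list(time = c(0, bh$time), surv = exp(-c(0, bh$hazard) * exp(s)))
    time_at_risk(cu, 100)$tar
  }, numeric(1))
  expect_true(all(diff(tars) <= 0))
})

test_that("swapping arm labels and heads negates every ITE", {
  dat <- linear_cox_data(250, seed = 5)
  cfg <- tiny_bsl_config(max_iterations = 50, balance_alpha = 0)
  m <- bsl_fit(dat$x, dat$time, dat$event, dat$treatment, cfg)
  m2 <- m
  swap <- function(nm) chartr("01", "10", nm)
  names(m2$params) <- ifelse(grepl("^h[01]_", names(m2$params)),
                             paste0(swap(substr(names(m2$params), 1, 2)),
                                    substring(names(m2$params), 3)),
                             names(m2$params))
  m2$baselines <- rev(m2$baselines)
  it1 <- compute_ite(m, dat$x[1:30, ], horizon = 80)
  it2 <- compute_ite(m2, dat$x[1:30, ], horizon = 80)
  expect_equal(it2$ite, -it1$ite)
})

test_that("null-effect cohorts give near-zero mean predicted ITE", {
  # shorter survival scale (median ~ 35 months) so the +-2 month bound is
  # meaningful relative to arm-specific baseline sampling noise
  devs <- vapply(1:3, function(sd_) {
    cfg <- compact_sim_config(2000, seed = sd_, effect = "null",
                              censoring = 0.3)
    cfg$baseline_hazard_scale <- 0.02
    co <- simulate_cohort(cfg)
    sp <- split_cohort(co, seed = sd_)
    enc <- encode_features(co, fit_on = sp$train_ids)
    tr <- which(co$id %in% sp$train_ids)
    te <- which(co$id %in% sp$test_ids)
    bcfg <- tiny_bsl_config(max_iterations = 600, patience_iterations = 150,
                            head_hidden_layers = integer(0),
                            shared_layers = c(8L), lasso_lambda = 0.05,
                            seed = sd_)
    m <- train_bsl(enc$x[tr, ], co$time[tr], co$event[tr], co$treatment[tr],
                   bcfg)
    it <- compute_ite(m, enc$x[te, ])
    mean(it$ite)
  }, numeric(1))
  # each seed stays small against the ~35-month median; their average is
  # centered within +-2 months of zero
  expect_true(all(abs(devs) < 8))
  expect_lt(abs(mean(devs)), 2)
})

test_that("strong planted benefit is detected for most Group A patients", {
  # CRT log hazard ratio -1 inside Group A, +0.3 outside: the sign of the
  # predicted ITE should agree with the true sign for at least 70% of the
  # held-out Group A patients
  co <- simulate_cohort(compact_sim_config(8000, seed = 70,
                                           effect = "strong"))
  sp <- split_cohort(co, seed = 70)
  enc <- encode_features(co, fit_on = sp$train_ids)
  tr <- which(co$id %in% sp$train_ids)
  te <- which(co$id %in% sp$test_ids)
  cfg <- tiny_bsl_config(shared_layers = c(16L), latent_dim = 8L,
                         head_hidden_layers = c(8L), lasso_lambda = 0.01,
                         learning_rate = 0.02, max_iterations = 500,
                         patience_iterations = 150, seed = 70)
  m <- train_bsl(enc$x[tr, ], co$time[tr], co$event[tr], co$treatment[tr],
                 cfg)
  it <- compute_ite(m, enc$x[te, ], ids = co$id[te])
  ab <- cohort_group_labels(co[te, ])
  agree <- sign(it$ite) == sign(co$true_ite_months[te])
  expect_gte(mean(agree[ab == "A"]), 0.7)
})

test_that("ITE tables round-trip through CSV", {
  bh <- make_basehaz(c(5, 25), c(0.4, 1.1))
  m <- zero_model(p = 2, basehaz0 = bh,
                  basehaz1 = make_basehaz(c(8, 30), c(0.3, 1.0)))
  it <- compute_ite(m, matrix(rnorm(10), 5, 2), horizon = 90)
  path <- tempfile(fileext = ".csv")
  write_ite(it, path)
  it2 <- read_ite(path)
  expect_equal(it2$ite, it$ite)
  expect_equal(it2$recommendation, it$recommendation)
})
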