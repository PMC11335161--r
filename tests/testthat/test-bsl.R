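test_that("configuration guards reject invalid hyperparameters", {
  expect_error(bsl_config(lasso_lambda = -1), "lasso_lambda")
  expect_error(bsl_config(hierarchy_M = 0), "M")
  expect_error(bsl_config(ot_epsilon = 0), "epsilon")
  expect_error(bsl_config(dropout_rate = 1), "dropout")
})

test_that("training refuses event-free arms and single-arm data", {
  dat <- linear_cox_data(60, seed = 1)
  cfg <- tiny_bsl_config(max_iterations = 5)
  ev <- dat$event
  ev[dat$treatment == 1] <- 0
  expect_error(bsl_fit(dat$x, dat$time, ev, dat$treatment, cfg), "no events")
  expect_error(bsl_fit(dat$x, dat$time, dat$event, rep(0, 60), cfg),
               "both treatment arms")
})

test_that("fixed seed and full-batch training give identical trajectories", {
  dat <- linear_cox_data(150, seed = 2)
  cfg <- tiny_bsl_config(max_iterations = 30, seed = 42)
  m1 <- bsl_fit(dat$x, dat$time, dat$event, dat$treatment, cfg)
  m2 <- bsl_fit(dat$x, dat$time, dat$event, dat$treatment, cfg)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
})

test_that("early stopping halts exactly at the configured patience", {
  dat <- linear_cox_data(120, seed = 3)
  # zero learning rate: the validation loss can never improve after the
  # first checkpoint, so training must stop after exactly `patience` more
  cfg <- tiny_bsl_config(learning_rate = 0, lasso_lambda = 0,
                         balance_alpha = 0, patience_iterations = 25,
                         max_iterations = 500)
  val <- list(x = dat$x[1:30, ], time = dat$time[1:30],
              event = dat$event[1:30], treatment = dat$treatment[1:30])
  m <- bsl_fit(dat$x[31:120, ], dat$time[31:120], dat$event[31:120],
               dat$treatment[31:120], cfg, validation = val)
  expect_equal(nrow(m$history), 26)       # best at iteration 1 + patience
  expect_equal(m$best_iter, 1L)
})

test_that("a huge lasso penalty empties both heads to constant scores", {
  dat <- linear_cox_data(100, seed = 4)
  cfg <- tiny_bsl_config(lasso_lambda = 1e5, balance_alpha = 0,
                         max_iterations = 10)
  m <- bsl_fit(dat$x, dat$time, dat$event, dat$treatment, cfg)
  for (arm in 0:1) {
    expect_equal(m$params[[paste0("h", arm, "_theta")]],
                 numeric(cfg$latent_dim))
    expect_equal(max(abs(m$params[[paste0("h", arm, "_W1")]])), 0)
    sc <- bsl_forward(m, dat$x[1:10, ], arm)
    expect_equal(diff(range(sc)), 0)
  }
})

test_that("no penalty with unbounded hierarchy keeps every feature active", {
  dat <- linear_cox_data(150, seed = 5)
  cfg <- tiny_bsl_config(lasso_lambda = 0, hierarchy_M = Inf,
                         max_iterations = 40)
  m <- bsl_fit(dat$x, dat$time, dat$event, dat$treatment, cfg)
  expect_length(bslnet:::dropped_features(m, 0), 0)
  expect_length(bslnet:::dropped_features(m, 1), 0)
})

test_that("the hierarchy constraint is feasible after training", {
  dat <- linear_cox_data(150, seed = 6)
  cfg <- tiny_bsl_config(lasso_lambda = 0.01, hierarchy_M = 2,
                         max_iterations = 40)
  m <- bsl_fit(dat$x, dat$time, dat$event, dat$treatment, cfg)
  for (arm in 0:1) {
    th <- m$params[[paste0("h", arm, "_theta")]]
    w1 <- m$params[[paste0("h", arm, "_W1")]]
    row_inf <- apply(abs(w1), 1, max)
    expect_true(all(row_inf <= 2 * abs(th) + 1e-10))
  }
})

test_that("a dropped feature is inert in both the linear and nonlinear path", {
  dat <- linear_cox_data(200, seed = 7)
  cfg <- tiny_bsl_config(shared_layers = integer(0), latent_dim = 4L,
                         head_hidden_layers = c(4L), lasso_lambda = 0.01,
                         balance_alpha = 0, max_iterations = 100)
  m <- bsl_fit(dat$x, dat$time, dat$event, dat$treatment, cfg)
  # drive one coordinate through the proximal operator at a huge penalty:
  # theta_j = 0 forces its whole first-layer row to zero
  j <- 2L
  pr <- hier_prox(m$params$h0_theta[j],
                  m$params$h0_W1[j, , drop = FALSE], lambda = 1e6,
                  m_const = m$config$hierarchy_M, step = 1)
  expect_equal(pr$theta, 0)
  expect_equal(max(abs(pr$w)), 0)
  m$params$h0_theta[j] <- pr$theta
  m$params$h0_W1[j, ] <- pr$w
  expect_true(j %in% bslnet:::dropped_features(m, 0))
  z <- bslnet:::forward_shared(m$params, m$config, dat$x[1:5, ], 0)$z
  s1 <- bslnet:::forward_head(m$params, m$config, 0, z, dat$x[1:5, ])$score
  z2 <- z; z2[, j] <- z2[, j] + 10
  s2 <- bslnet:::forward_head(m$params, m$config, 0, z2, dat$x[1:5, ])$score
  expect_equal(s1, s2)
})

test_that("per-arm risk recovery on linear Cox data reaches C-index 0.70", {
  dat <- linear_cox_data(1200, seed = 8)
  tr <- 1:900; te <- 901:1200
  cfg <- tiny_bsl_config(shared_layers = integer(0), latent_dim = 4L,
                         head_hidden_layers = integer(0),
                         lasso_lambda = 0.002, balance_alpha = 0,
                         learning_rate = 0.05, max_iterations = 400,
                         patience_iterations = 400)
  m <- bsl_fit(dat$x[tr, ], dat$time[tr], dat$event[tr], dat$treatment[tr],
               cfg)
  for (arm in 0:1) {
    idx <- te[dat$treatment[te] == arm]
    true_c <- c_index(dat$lp[idx], dat$time[idx], dat$event[idx])
    model_c <- c_index(bsl_forward(m, dat$x[idx, ], arm),
                       dat$time[idx], dat$event[idx])
    expect_gte(true_c, 0.75)    # the generative model is informative enough
    expect_gte(model_c, 0.70)
  }
})

test_that("balancing shrinks the held-out latent divergence", {
  deltas <- vapply(1:3, function(sd_) {
    co <- simulate_cohort(compact_sim_config(500, seed = 40 + sd_))
    enc <- encode_features(co)
    tr <- 1:400; te <- 401:500
    fit_alpha <- function(a) {
      cfg <- tiny_bsl_config(balance_alpha = a, max_iterations = 80,
                             seed = sd_)
      m <- bsl_fit(enc$x[tr, ], co$time[tr], co$event[tr], co$treatment[tr],
                   cfg)
      z <- bsl_latent(m, enc$x[te, ])
      ot_balance_loss(z[co$treatment[te] == 0, , drop = FALSE],
                      z[co$treatment[te] == 1, , drop = FALSE], 0.5)
    }
    fit_alpha(0) - fit_alpha(10)
  }, numeric(1))
  expect_true(all(deltas > 0))
})

test_that("a checkpoint restores predictions exactly", {
  dat <- linear_cox_data(150, seed = 9)
  cfg <- tiny_bsl_config(max_iterations = 30)
  m <- bsl_fit(dat$x, dat$time, dat$event, dat$treatment, cfg)
  path <- tempfile(fileext = ".json")
  write_bsl(m, path)
  m2 <- read_bsl(path)
  for (arm in 0:1) {
    expect_equal(bsl_forward(m2, dat$x[1:20, ], arm),
                 bsl_forward(m, dat$x[1:20, ], arm), tolerance = 1e-12)
  }
  it1 <- compute_ite(m, dat$x[1:20, ], horizon = 80)
  it2 <- compute_ite(m2, dat$x[1:20, ], horizon = 80)
  expect_equal(it1$ite, it2$ite)
})

test_that("cross-validated tuning selects from the grid and records scores", {
  dat <- linear_cox_data(250, seed = 10)
  cfg <- tiny_bsl_config(max_iterations = 25, patience_iterations = 25)
  folds <- make_cv_folds(seq_len(250), k = 5, seed = 1)
  m <- train_bsl(dat$x, dat$time, dat$event, dat$treatment, cfg,
                 folds = folds,
                 tune_grid = list(lasso_lambda = c(0, 0.05)))
  expect_s3_class(m, "bsl_model")
  expect_equal(nrow(m$cv_results), 2)
  expect_true(m$config$lasso_lambda %in% c(0, 0.05))
  expect_equal(m$config$lasso_lambda,
               m$cv_results$lasso_lambda[which.min(m$cv_results$cv_loss)])
})
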