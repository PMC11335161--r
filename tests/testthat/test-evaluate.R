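test_that("group assignment follows exact matching and reports n_rec", {
  ga <- assign_groups(c(1, 0, 1), c("CRT", "CRT", "RT"))
  expect_equal(as.character(ga$group), c("Rec", "Anti-rec", "Anti-rec"))
  expect_equal(attr(ga, "n_rec"), 1L)
  all_match <- assign_groups(c(0, 1, 1), c(0, 1, 1))
  expect_equal(attr(all_match, "n_rec"), 3L)
  expect_error(assign_groups(c(0, 1), c(0)), "lengths")
})

test_that("propensity model recovers stratum frequencies and clips", {
  # saturated single binary covariate: fitted values are stratum shares
  x <- matrix(c(rep(1, 100), rep(0, 100)), ncol = 1)
  g <- c(rbinom(0, 1, 0), rep(c(1, 0), c(30, 70)), rep(c(1, 0), c(70, 30)))
  p <- estimate_propensity(x, g)
  expect_equal(unique(round(p[1:100], 6)), 0.30)
  expect_equal(unique(round(p[101:200], 6)), 0.70)
  # independence: probabilities concentrate near prevalence
  set.seed(2)
  x2 <- matrix(rnorm(4000), ncol = 2)
  g2 <- rbinom(2000, 1, 0.35)
  p2 <- estimate_propensity(x2, g2)
  expect_lt(abs(mean(p2) - mean(g2)), 0.01)
  expect_lt(sd(p2), 0.05)
  # clamping at the configured bounds
  x3 <- matrix(c(rnorm(50, -3), rnorm(50, 3)), ncol = 1)
  g3 <- rep(0:1, each = 50)
  expect_warning(p3 <- estimate_propensity(x3, g3), "separation")
  expect_true(all(p3 >= 0.01 & p3 <= 0.99))
})

test_that("IPTW weights follow their closed forms", {
  expect_equal(iptw_weights(0.5, 1, stabilized = FALSE, truncate = NULL), 2)
  expect_equal(iptw_weights(0.5, 0, stabilized = FALSE, truncate = NULL), 2)
  expect_equal(iptw_weights(0.99, 1, stabilized = FALSE, truncate = NULL),
               1 / 0.99)
  set.seed(4)
  e <- runif(500, 0.2, 0.8)
  g <- rbinom(500, 1, e)
  ws <- iptw_weights(e, g, stabilized = TRUE)
  expect_gt(mean(ws), 0.9)
  expect_lt(mean(ws), 1.1)
  expect_true(all(ws > 0))
})

test_that("SMD matches the hand formula and reweighting oracle", {
  # binary covariate at prevalences 0.5 vs 0.3
  x <- matrix(rep(c(1, 0, 1, 0), c(50, 50, 30, 70)), ncol = 1)
  g <- rep(c(1, 0), each = 100)
  expect_equal(unname(smd(x, g)),
               (0.5 - 0.3) / sqrt((0.25 + 0.21) / 2), tolerance = 1e-12)
  # identical groups have zero SMD
  set.seed(5)
  xx <- cbind(rnorm(100), rbinom(100, 1, 0.4))
  expect_equal(unname(smd(rbind(xx, xx), rep(0:1, each = 100))), c(0, 0))
  # weights constructed to equalize the two groups exactly
  x2 <- matrix(rep(c(1, 0, 1, 0), c(60, 40, 20, 80)), ncol = 1)
  g2 <- rep(c(1, 0), each = 100)
  w2 <- ifelse(g2 == 1, 1, ifelse(x2[, 1] == 1, 60 / 20, 40 / 80))
  expect_lt(abs(smd(x2, g2, weights = w2)), 1e-12)
})

test_that("cox_hr direction, weighting degeneracy and consistency", {
  set.seed(6)
  n <- 5000
  g <- rep(0:1, each = n / 2)
  t <- rexp(n, 0.02 * ifelse(g == 1, 0.5, 1))
  e <- rep(1L, n)
  grp <- factor(g, levels = 0:1, labels = c("Anti-rec", "Rec"))
  fit <- cox_hr(t, e, grp)
  expect_gt(fit$hr, 0.45); expect_lt(fit$hr, 0.56)
  expect_true(fit$ci[1] < fit$hr && fit$hr < fit$ci[2])
  # unit weights equal the unweighted fit
  fitw <- cox_hr(t, e, grp, weights = rep(1, n))
  expect_equal(fitw$hr, fit$hr, tolerance = 1e-6)
  expect_error(cox_hr(c(1, 2), c(1, 0), factor(c("a", "b"))), "no events")
})

test_that("RMST difference matches the exponential closed form", {
  set.seed(7)
  lam <- log(2) / 24
  n <- 30000
  t <- rexp(n, lam)
  g <- factor(rep(c("Anti-rec", "Rec"), each = n / 2))
  rs <- rmst_difference(t, rep(1, n), g, tau = 60)
  closed <- (1 - exp(-lam * 60)) / lam
  expect_lt(abs(rs$rmst[1] - closed) / closed, 0.03)
  expect_lt(abs(rs$rmst[2] - closed) / closed, 0.03)
  expect_lt(abs(rs$drmst), 1.5)
  expect_true(rs$ci[1] < rs$drmst & rs$drmst < rs$ci[2])
  expect_error(rmst_difference(t / 100, rep(1, n), g, tau = 60), "exceeds")
})

test_that("DRMST equals independent trapezoid integration of the KM curves", {
  set.seed(8)
  n <- 400
  t <- c(rexp(n / 2, 0.02), rexp(n / 2, 0.035))
  e <- rbinom(n, 1, 0.8)
  g <- factor(rep(c("a", "b"), each = n / 2))
  tau <- min(tapply(t, g, max))
  rs <- rmst_difference(t, e, g, tau = tau)
  # step-function integral of each group's KM, computed independently
  step_area <- function(idx) {
    km <- survival::survfit(survival::Surv(t[idx], e[idx]) ~ 1)
    tt <- c(0, km$time[km$time <= tau], tau)
    ss <- c(1, km$surv[km$time <= tau])
    sum(diff(tt) * ss)
  }
  d_oracle <- step_area(g == "b") - step_area(g == "a")
  expect_equal(rs$drmst, d_oracle, tolerance = 1e-8)
})

test_that("log-rank: identical groups, KM reduction, small-sample oracle", {
  t <- c(5, 8, 12, 5, 8, 12); e <- rep(1, 6)
  g <- factor(rep(c("a", "b"), each = 3))
  res <- km_logrank(t, e, g, horizons = 60)
  expect_equal(res$tests$chisq, 0)
  expect_equal(res$tests$p, 1)
  # uncensored KM equals the empirical survival fraction
  cu <- res$curves[res$curves$group == "a", ]
  expect_equal(cu$surv, c(1, 2 / 3, 1 / 3, 0))
  # six-subject hand-computable instance vs the O-E oracle and survdiff
  t2 <- c(3, 5, 7, 2, 4, 9); e2 <- c(1, 0, 1, 1, 1, 0)
  g2 <- factor(rep(c("a", "b"), each = 3))
  res2 <- km_logrank(t2, e2, g2, horizons = 100)
  orc <- logrank_oracle(t2, e2, g2)
  expect_equal(res2$tests$chisq, orc$chisq, tolerance = 1e-12)
  sd2 <- survival::survdiff(survival::Surv(t2, e2) ~ g2)
  expect_equal(res2$tests$chisq, sd2$chisq, tolerance = 1e-10)
})

test_that("weighted log-rank reduces to the classical test at unit weights", {
  set.seed(9)
  n <- 120
  t <- rexp(n, 0.03); e <- rbinom(n, 1, 0.7)
  g <- factor(sample(c("a", "b"), n, replace = TRUE))
  r1 <- km_logrank(t, e, g, weights = rep(1, n), horizons = 200)
  sd1 <- survival::survdiff(survival::Surv(pmin(t, 200),
                                           ifelse(t > 200, 0, e)) ~ g)
  expect_equal(r1$tests$chisq, sd1$chisq, tolerance = 1e-10)
})

test_that("concordance index agrees with exhaustive pair counting", {
  # perfect ordering and its reversal
  t <- c(1, 2, 3, 4, 5); e <- rep(1, 5)
  expect_equal(c_index(c(5, 4, 3, 2, 1), t, e), 1)
  expect_equal(c_index(c(1, 2, 3, 4, 5), t, e), 0)
  set.seed(10)
  for (rep in 1:5) {
    n <- 12
    tt <- rexp(n); ee <- rbinom(n, 1, 0.6); ee[1] <- 1
    ss <- rnorm(n)
    expect_equal(c_index(ss, tt, ee), cindex_oracle(ss, tt, ee),
                 tolerance = 1e-12)
  }
  expect_error(c_index(c(1, 2), c(5, 7), c(0, 0)), "comparable")
})

test_that("integrated Brier score: closed forms and brute-force oracle", {
  # constant prediction 0.5 with no censoring: Brier = 0.25 everywhere
  set.seed(11)
  t <- runif(40, 1, 99); e <- rep(1, 40)
  grid <- seq(0, 100, by = 1)
  sp <- matrix(0.5, 40, length(grid))
  expect_equal(integrated_brier(sp, grid, t, e, tau = 80), 0.25,
               tolerance = 1e-6)
  # oracle step predictions dropping at the true event time: near zero
  sp_oracle <- t(vapply(t, function(ti) as.numeric(grid < ti),
                        numeric(length(grid))))
  expect_lt(integrated_brier(sp_oracle, grid, t, e, tau = 80), 0.02)
  # random censored instance vs the naive double-sum oracle
  n <- 14
  t2 <- runif(n, 1, 50); e2 <- rbinom(n, 1, 0.6)
  grid2 <- seq(0, 50, by = 2.5)
  sp2 <- matrix(runif(n * length(grid2)), n)
  sp2 <- t(apply(sp2, 1, function(r) rev(sort(r))))
  expect_equal(integrated_brier(sp2, grid2, t2, e2, tau = 40),
               ibs_oracle(sp2, grid2, t2, e2, tau = 40), tolerance = 1e-10)
})

test_that("full report on a compact cohort is coherent and flags balance", {
  co <- simulate_cohort(compact_sim_config(500, seed = 20))
  # recommendations from the ground truth
  ite <- data.frame(id = co$id, tar_rt = 0, tar_crt = 0,
                    ite = co$true_ite_months,
                    recommendation = ifelse(co$true_ite_months > 0,
                                            "CRT", "RT"))
  rep <- evaluate_recommendations(co, ite, tau = 36)
  expect_s3_class(rep, "bsl_eval_report")
  expect_true(rep$hr$ci[1] < rep$hr$hr & rep$hr$hr < rep$hr$ci[2])
  expect_true(rep$hr_a$ci[1] < rep$hr_a$hr & rep$hr_a$hr < rep$hr_a$ci[2])
  expect_equal(rep$n_rec + sum(rep$groups$group == "Anti-rec"), 500)
  expect_true(all(rep$smd$covariate != ""))
  expect_output(print(rep), "Recommendation effectiveness")
  # degenerate grouping errors out explicitly
  ite_all <- ite
  ite_all$recommendation <- ifelse(co$treatment == 1, "CRT", "RT")
  expect_error(evaluate_recommendations(co, ite_all), "degenerate")
})
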