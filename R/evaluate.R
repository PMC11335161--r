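#' Recommendation-concordance grouping
#'
#' Patients whose received treatment matches the model's recommendation form
#' the "Rec" group; the others form "Anti-rec".
#'
#' @param actual Received treatments (0/1 or "RT"/"CRT").
#' @param recommended Recommended treatments, same coding.
#' @param ids Optional patient ids.
#' @return A `data.frame` with `id`, `actual`, `recommended` and `group`
#'   (factor, levels `Anti-rec`, `Rec`); the number of Rec patients is in
#'   `attr(, "n_rec")`.
#' @export
assign_groups <- function(actual, recommended, ids = NULL) {
  if (length(actual) != length(recommended)) {
    stop_bsl("actual and recommended have different lengths (%d vs %d)",
             length(actual), length(recommended))
  }
  norm <- function(v) {
    if (is.numeric(v)) ifelse(v == 1, "CRT", "RT") else as.character(v)
  }
  a <- norm(actual); r <- norm(recommended)
  grp <- factor(ifelse(a == r, "Rec", "Anti-rec"),
                levels = c("Anti-rec", "Rec"))
  out <- data.frame(id = ids %||% seq_along(a), actual = a, recommended = r,
                    group = grp)
  attr(out, "n_rec") <- sum(grp == "Rec")
  out
}

#' Design matrix for the propensity / adjustment models
#'
#' One-hot encodes the cohort covariates *dropping one reference level per
#' block* (unlike the network encoding), so Cox and logistic fits stay
#' identifiable; continuous covariates are left on their raw scale.
#'
#' @param cohort Cohort `data.frame`.
#' @param columns Covariate columns; defaults to [covariate_columns()]
#'   without `region`.
#' @return Numeric model matrix without intercept column.
#' @export
cohort_design <- function(cohort,
                          columns = setdiff(covariate_columns(cohort),
                                            "region")) {
  df <- cohort[columns]
  df[] <- lapply(df, function(v) if (is.character(v)) factor(v) else v)
  mm <- stats::model.matrix(~ ., data = df)
  mm[, -1, drop = FALSE]
}

#' Propensity scores from a main-effects logistic regression
#'
#' @param x Numeric covariate matrix.
#' @param group 0/1 group membership (or logical / two-level factor).
#' @param clip Probability clipping bounds. Default `c(0.01, 0.99)`.
#' @return Fitted probabilities in `[clip[1], clip[2]]`, with the fitted
#'   `glm` in `attr(, "model")`.
#' @export
estimate_propensity <- function(x, group, clip = c(0.01, 0.99)) {
  g <- if (is.factor(group)) as.integer(group) - 1L else as.integer(group)
  if (length(unique(g)) < 2) stop_bsl("both groups must be present")
  df <- data.frame(.g = g, x, check.names = TRUE)
  fit <- suppressWarnings(stats::glm(.g ~ ., data = df, family = stats::binomial()))
  p <- stats::fitted(fit)
  if (any(p < 1e-8 | p > 1 - 1e-8)) {
    warn_bsl("propensity model close to perfect separation; probabilities clipped")
  }
  out <- pmin(pmax(p, clip[1]), clip[2])
  attr(out, "model") <- fit
  out
}

#' Inverse probability of treatment weights
#'
#' Unstabilized weights are `g/e + (1-g)/(1-e)`; stabilized weights multiply
#' each term by the marginal group prevalence, keeping the weighted sample
#' size near the original. Weights are truncated at the requested
#' percentiles (1st/99th by default).
#'
#' @param propensity Probabilities in (0, 1) of membership in group 1.
#' @param group 0/1 membership.
#' @param stabilized Multiply by marginal prevalences (default `TRUE`).
#' @param truncate Percentile bounds for weight truncation, or `NULL`.
#' @return Positive weights, one per subject.
#' @export
iptw_weights <- function(propensity, group, stabilized = TRUE,
                         truncate = c(0.01, 0.99)) {
  e <- as.numeric(propensity)
  if (any(e <= 0 | e >= 1)) stop_bsl("propensity must lie strictly in (0, 1)")
  g <- if (is.factor(group)) as.integer(group) - 1L else as.integer(group)
  w <- g / e + (1 - g) / (1 - e)
  if (stabilized) {
    p1 <- mean(g)
    w <- w * ifelse(g == 1, p1, 1 - p1)
  }
  if (!is.null(truncate)) {
    q <- stats::quantile(w, truncate)
    w <- pmin(pmax(w, q[1]), q[2])
  }
  w
}

weighted_mean_var <- function(x, w) {
  m <- sum(w * x) / sum(w)
  v <- sum(w * (x - m)^2) / sum(w)
  c(mean = m, var = v)
}

#' Standardized mean differences between two groups
#'
#' For each covariate column, `(m1 - m0) / sqrt((s1^2 + s0^2) / 2)`, with
#' weighted means and variances when weights are given. Binary (0/1) columns
#' use the proportion variance `p (1 - p)`.
#'
#' @param x Numeric covariate matrix.
#' @param group 0/1 membership.
#' @param weights Optional positive weights.
#' @return Named numeric vector of SMDs (signed; group 1 minus group 0).
#' @export
smd <- function(x, group, weights = NULL) {
  x <- as.matrix(x)
  g <- if (is.factor(group)) as.integer(group) - 1L else as.integer(group)
  if (length(unique(g)) < 2) stop_bsl("both groups must be present")
  w <- weights %||% rep(1, length(g))
  out <- numeric(ncol(x))
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    binary <- is_binary01(v)
    mv1 <- weighted_mean_var(v[g == 1], w[g == 1])
    mv0 <- weighted_mean_var(v[g == 0], w[g == 0])
    if (binary) {
      s2 <- (mv1["mean"] * (1 - mv1["mean"]) +
               mv0["mean"] * (1 - mv0["mean"])) / 2
    } else {
      s2 <- (mv1["var"] + mv0["var"]) / 2
    }
    if (s2 <= 0) {
      warn_bsl("zero pooled variance for column %s; SMD set to 0",
               colnames(x)[j] %||% j)
      out[j] <- 0
    } else {
      out[j] <- unname((mv1["mean"] - mv0["mean"]) / sqrt(s2))
    }
  }
  stats::setNames(out, colnames(x))
}

#' Cox proportional hazards ratio between two groups
#'
#' Hazard ratio of the second factor level relative to the first (for
#' Rec/Anti-rec grouping, Rec vs the Anti-rec reference, so HR < 1 means
#' following the recommendation is protective). With weights, a robust
#' sandwich variance is used.
#'
#' @param times,events Survival outcome.
#' @param group Two-level factor (first level = reference) or 0/1.
#' @param covariates Optional numeric matrix of adjustment covariates.
#' @param weights Optional IPTW weights.
#' @return List with `hr`, `ci` (length 2), `p`, `n`, and the fitted model.
#' @export
cox_hr <- function(times, events, group, covariates = NULL, weights = NULL) {
  g <- if (is.factor(group)) group else factor(group)
  if (nlevels(droplevels(g)) != 2) stop_bsl("group must have two levels")
  for (lev in levels(droplevels(g))) {
    if (sum(events[g == lev]) == 0) {
      stop_bsl("group '%s' has no events", lev)
    }
  }
  df <- data.frame(.t = times, .e = events, .g = g)
  rhs <- ".g"
  if (!is.null(covariates)) {
    cv <- as.matrix(covariates)
    colnames(cv) <- paste0("c", seq_len(ncol(cv)))
    df <- cbind(df, cv)
    rhs <- paste(c(".g", colnames(cv)), collapse = " + ")
  }
  fit <- tryCatch(
    survival::coxph(stats::as.formula(paste("survival::Surv(.t, .e) ~", rhs)),
                    data = df, weights = weights,
                    robust = !is.null(weights)),
    warning = function(w) {
      if (grepl("did not converge", conditionMessage(w))) {
        stop_bsl("Cox model did not converge: %s", conditionMessage(w))
      }
      suppressWarnings(
        survival::coxph(stats::as.formula(
          paste("survival::Surv(.t, .e) ~", rhs)),
          data = df, weights = weights, robust = !is.null(weights)))
    })
  sm <- summary(fit)
  i <- 1L  # the group indicator is the first coefficient
  list(hr = unname(sm$conf.int[i, "exp(coef)"]),
       ci = unname(sm$conf.int[i, c("lower .95", "upper .95")]),
       p = unname(sm$coefficients[i, ncol(sm$coefficients)]),
       n = length(times),
       model = fit)
}

# rmean and its se from a survfit, one row per group
survfit_rmst <- function(fit, tau) {
  tab <- summary(fit, rmean = tau)$table
  if (is.null(dim(tab))) tab <- matrix(tab, nrow = 1, dimnames = list(
    "all", names(tab)))
  rm_col <- grep("rmean", colnames(tab))
  list(rmean = tab[, rm_col[1]], se = tab[, rm_col[2]])
}

#' Difference in restricted mean survival time between two groups
#'
#' Area under each group's (optionally IPTW-weighted) Kaplan-Meier curve up
#' to `tau` months; the difference is second level minus first level
#' (Rec minus Anti-rec for recommendation grouping). The default confidence
#' interval combines the two groups' Greenwood-based RMST standard errors;
#' set `boot > 0` for a bootstrap interval instead.
#'
#' @param times,events Survival outcome.
#' @param group Two-level factor or 0/1.
#' @param tau Horizon in months (default 60); must not exceed either group's
#'   maximum follow-up.
#' @param weights Optional IPTW weights.
#' @param boot Number of bootstrap replicates for the CI (0 = analytic).
#' @param conf Confidence level.
#' @return List with `drmst`, `ci`, `rmst` (per group), `tau`.
#' @export
rmst_difference <- function(times, events, group, tau = 60, weights = NULL,
                            boot = 0, conf = 0.95) {
  g <- if (is.factor(group)) droplevels(group) else factor(group)
  for (lev in levels(g)) {
    if (max(times[g == lev]) < tau) {
      stop_bsl("tau = %g exceeds the maximum follow-up (%g) in group '%s'",
               tau, max(times[g == lev]), lev)
    }
  }
  w <- weights %||% rep(1, length(times))
  df <- data.frame(.t = times, .e = events, .g = g, .w = w)
  fit <- survival::survfit(survival::Surv(.t, .e) ~ .g, data = df,
                           weights = .w)
  rs <- survfit_rmst(fit, tau)
  d <- unname(rs$rmean[2] - rs$rmean[1])
  z <- stats::qnorm(1 - (1 - conf) / 2)
  if (boot > 0) {
    n <- length(times)
    bd <- vapply(seq_len(boot), function(b) {
      ii <- sample.int(n, n, replace = TRUE)
      bf <- survival::survfit(survival::Surv(.t, .e) ~ .g, data = df[ii, ],
                              weights = .w)
      if (length(unique(df$.g[ii])) < 2) return(NA_real_)
      brs <- survfit_rmst(bf, min(tau, min(tapply(df$.t[ii], df$.g[ii], max))))
      unname(brs$rmean[2] - brs$rmean[1])
    }, numeric(1))
    ci <- unname(stats::quantile(bd, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                                 na.rm = TRUE))
  } else {
    se <- sqrt(sum(rs$se^2))
    ci <- c(d - z * se, d + z * se)
  }
  list(drmst = d, ci = ci,
       rmst = stats::setNames(as.numeric(rs$rmean), levels(g)), tau = tau)
}

# weighted KM curve per group at the pooled event times
weighted_km <- function(times, events, group, weights) {
  out <- list()
  for (lev in levels(group)) {
    idx <- group == lev
    t <- times[idx]; e <- events[idx]; w <- weights[idx]
    et <- sort(unique(t[e == 1]))
    surv <- numeric(length(et)); s <- 1
    for (k in seq_along(et)) {
      at_risk <- sum(w[t >= et[k]])
      d <- sum(w[t == et[k] & e == 1])
      if (at_risk > 0) s <- s * (1 - d / at_risk)
      surv[k] <- s
    }
    out[[lev]] <- data.frame(group = lev, time = c(0, et), surv = c(1, surv))
  }
  do.call(rbind, out)
}

# weighted log-rank statistic (reduces to the classical test at unit weights)
weighted_logrank <- function(times, events, group, weights) {
  lev <- levels(group)
  et <- sort(unique(times[events == 1]))
  o_minus_e <- 0; v <- 0
  for (tt in et) {
    at <- times >= tt
    yw <- sum(weights[at])
    y1 <- sum(weights[at & group == lev[2]])
    dw <- sum(weights[times == tt & events == 1])
    d1 <- sum(weights[times == tt & events == 1 & group == lev[2]])
    if (yw <= 0) next
    o_minus_e <- o_minus_e + (d1 - dw * y1 / yw)
    if (yw > 1) {
      v <- v + dw * (y1 / yw) * (1 - y1 / yw) * (yw - dw) / (yw - 1)
    }
  }
  chisq <- if (v > 0) o_minus_e^2 / v else 0
  list(chisq = chisq, p = stats::pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Kaplan-Meier curves and log-rank tests at fixed horizons
#'
#' Computes (optionally IPTW-weighted) Kaplan-Meier curves for two groups
#' and log-rank tests on data administratively censored at each horizon.
#' With unit weights the test is the classical log-rank.
#'
#' @param times,events Survival outcome.
#' @param group Two-level factor or 0/1.
#' @param weights Optional IPTW weights.
#' @param horizons Months at which to test (default 5 and 10 years).
#' @return List with `curves` (data.frame: group, time, surv) and `tests`
#'   (data.frame: horizon, chisq, p).
#' @export
km_logrank <- function(times, events, group, weights = NULL,
                       horizons = c(60, 120)) {
  g <- if (is.factor(group)) droplevels(group) else factor(group)
  if (nlevels(g) != 2) stop_bsl("group must have two levels")
  if (any(table(g) == 0)) stop_bsl("a group has zero subjects")
  w <- weights %||% rep(1, length(times))
  curves <- weighted_km(times, events, g, w)
  tests <- do.call(rbind, lapply(horizons, function(h) {
    tt <- pmin(times, h)
    ee <- ifelse(times > h, 0L, events)
    lr <- weighted_logrank(tt, ee, g, w)
    data.frame(horizon = h, chisq = lr$chisq, p = lr$p)
  }))
  list(curves = curves, tests = tests)
}

#' Harrell's concordance index
#'
#' Probability that, of two comparable subjects, the one with the higher
#' risk score fails earlier. Tied scores count one half.
#'
#' @param scores Risk scores (higher = predicted earlier failure).
#' @param times,events Survival outcome.
#' @return Value in `[0, 1]`.
#' @export
c_index <- function(scores, times, events) {
  fit <- survival::concordance(survival::Surv(times, events) ~ scores,
                               reverse = TRUE)
  cnt <- fit$count
  comparable <- sum(cnt[c("concordant", "discordant", "tied.x")])
  if (comparable == 0) stop_bsl("no comparable pairs")
  unname(fit$concordance)
}

# step-function evaluation of a KM fit (right-continuous), optionally the
# left limit G(t-)
km_eval <- function(km_time, km_surv, t, left = FALSE) {
  if (!length(km_time)) return(rep(1, length(t)))
  idx <- if (left) findInterval(t, km_time, left.open = TRUE)
  else findInterval(t, km_time)
  c(1, km_surv)[idx + 1L]
}

#' Integrated Brier score with IPCW censoring weights
#'
#' The Brier score at time t weights observed outcomes by the inverse of the
#' censoring-survival function G (Kaplan-Meier of the censoring times):
#' subjects who died by t contribute `S_i(t)^2 / G(T_i-)`, subjects still at
#' risk contribute `(1 - S_i(t))^2 / G(t)`, and subjects censored by t drop
#' out. Scores are integrated over `[0, tau]` by the trapezoid rule and
#' normalized by `tau`.
#'
#' @param surv_pred Matrix of predicted survival probabilities, one row per
#'   subject, columns on `pred_times`.
#' @param pred_times Ascending time grid covering `[0, tau]`.
#' @param times,events Observed outcome.
#' @param tau Integration horizon (months).
#' @return Single value in `[0, 1]`.
#' @export
integrated_brier <- function(surv_pred, pred_times, times, events, tau) {
  surv_pred <- as.matrix(surv_pred)
  stopifnot(ncol(surv_pred) == length(pred_times),
            nrow(surv_pred) == length(times))
  if (max(pred_times) < tau) stop_bsl("prediction grid must cover [0, tau]")
  cens_fit <- survival::survfit(survival::Surv(times, 1 - events) ~ 1)
  gt <- cens_fit$time; gs <- cens_fit$surv
  grid <- pred_times[pred_times <= tau]
  if (max(grid) < tau) grid <- c(grid, tau)
  g_at <- km_eval(gt, gs, grid)
  g_at_ti <- km_eval(gt, gs, times, left = TRUE)
  if (any(g_at <= 0)) {
    warn_bsl("censoring KM reaches 0 before tau; integration truncated")
    keep <- g_at > 0
    grid <- grid[keep]; g_at <- g_at[keep]
  }
  bs <- vapply(seq_along(grid), function(k) {
    t <- grid[k]
    sp <- surv_pred[, findInterval(t, pred_times)]
    died <- times <= t & events == 1
    alive <- times > t
    contrib <- numeric(length(times))
    contrib[died] <- sp[died]^2 / g_at_ti[died]
    contrib[alive] <- (1 - sp[alive])^2 / g_at[k]
    mean(contrib)
  }, numeric(1))
  sum(diff(grid) * (bs[-1] + bs[-length(bs)]) / 2) / tau
}

#' Full recommendation-effectiveness report
#'
#' Implements the evaluation framework for a test cohort and its ITE table:
#' Rec/Anti-rec grouping; a main-effects logistic propensity for Rec
#' membership on all covariates *including the received treatment* (surgery
#' enters through the resection covariate); stabilized, truncated IPTW
#' weights; unadjusted, covariate-adjusted and IPTW-adjusted hazard ratios of
#' Rec vs Anti-rec; 5-year DRMST unweighted and weighted; weighted and
#' unweighted KM curves with log-rank tests at 5 and 10 years; pre/post
#' weighting SMD tables (flagged above 0.1); and, when the model and encoded
#' features are supplied, per-arm concordance and integrated Brier scores.
#'
#' @param cohort Test cohort `data.frame`.
#' @param ite ITE table from [compute_ite()] aligned with `cohort` (matched
#'   by `id`).
#' @param model Optional fitted `bsl_model` (enables C-index/IBS).
#' @param x Optional encoded feature matrix aligned with `cohort` (required
#'   for C-index/IBS).
#' @param tau RMST and IBS horizon in months (default 60).
#' @param horizons Log-rank horizons (default 60 and 120 months).
#' @return Object of class `bsl_eval_report`.
#' @export
evaluate_recommendations <- function(cohort, ite, model = NULL, x = NULL,
                                     tau = 60, horizons = c(60, 120)) {
  assert_cols(cohort, c("id", "treatment", "time", "event"))
  ite <- ite[match(cohort$id, ite$id), ]
  if (anyNA(ite$recommendation)) {
    stop_bsl("ITE table does not cover every test patient")
  }
  ga <- assign_groups(cohort$treatment, ite$recommendation, ids = cohort$id)
  if (any(table(ga$group) == 0)) {
    stop_bsl("degenerate report: the %s group is empty",
             names(which(table(ga$group) == 0))[1])
  }
  design <- cohort_design(cohort)
  design_full <- cbind(design, treatment = cohort$treatment)
  rec01 <- as.integer(ga$group == "Rec")

  prop <- estimate_propensity(design_full, rec01)
  wts <- iptw_weights(prop, rec01)

  smd_pre <- smd(design_full, rec01)
  smd_post <- smd(design_full, rec01, weights = wts)

  hr <- cox_hr(cohort$time, cohort$event, ga$group)
  hr_cov <- cox_hr(cohort$time, cohort$event, ga$group, covariates = design_full)
  hr_a <- cox_hr(cohort$time, cohort$event, ga$group, weights = wts)

  tau_eff <- min(tau, tapply(cohort$time, ga$group, max))
  drmst <- rmst_difference(cohort$time, cohort$event, ga$group, tau = tau_eff)
  drmst_a <- rmst_difference(cohort$time, cohort$event, ga$group,
                             tau = tau_eff, weights = wts)

  km <- km_logrank(cohort$time, cohort$event, ga$group, horizons = horizons)
  km_a <- km_logrank(cohort$time, cohort$event, ga$group, weights = wts,
                     horizons = horizons)

  cindex <- ibs <- NULL
  if (!is.null(model) && !is.null(x)) {
    cindex <- numeric(2); ibs <- numeric(2)
    names(cindex) <- names(ibs) <- c("RT", "CRT")
    for (arm in 0:1) {
      idx <- which(cohort$treatment == arm)
      sc <- bsl_forward(model, x[idx, , drop = FALSE], arm)
      cindex[arm + 1] <- c_index(sc, cohort$time[idx], cohort$event[idx])
      bh <- model$baselines[[arm + 1]]
      grid <- c(0, bh$time)
      haz <- c(0, bh$hazard)
      sp <- exp(-outer(exp(sc), haz))
      tau_arm <- min(tau, max(cohort$time[idx]))
      ibs[arm + 1] <- integrated_brier(sp, grid, cohort$time[idx],
                                       cohort$event[idx], tau_arm)
    }
  }

  structure(list(
    groups = ga,
    n_rec = attr(ga, "n_rec"),
    propensity = prop,
    weights = wts,
    smd = data.frame(covariate = names(smd_pre),
                     smd_unweighted = unname(smd_pre),
                     smd_weighted = unname(smd_post),
                     balanced = abs(smd_post) < 0.1),
    hr = hr, hr_cov = hr_cov, hr_a = hr_a,
    drmst = drmst, drmst_a = drmst_a,
    km = km, km_a = km_a,
    c_index = cindex, ibs = ibs,
    tau = tau_eff, horizons = horizons
  ), class = "bsl_eval_report")
}

#' @export
print.bsl_eval_report <- function(x, ...) {
  cat("Recommendation effectiveness report\n")
  cat(sprintf("  n = %d (Rec: %d, Anti-rec: %d)\n",
              nrow(x$groups), x$n_rec, nrow(x$groups) - x$n_rec))
  fmt <- function(h) sprintf("%.2f (95%% CI %.2f-%.2f)", h$hr, h$ci[1], h$ci[2])
  cat("  HR   (Rec vs Anti-rec):", fmt(x$hr), "\n")
  cat("  HR^a (IPTW):           ", fmt(x$hr_a), "\n")
  cat(sprintf("  DRMST   at %g mo: %.2f (95%% CI %.2f-%.2f)\n",
              x$tau, x$drmst$drmst, x$drmst$ci[1], x$drmst$ci[2]))
  cat(sprintf("  DRMST^a at %g mo: %.2f (95%% CI %.2f-%.2f)\n",
              x$tau, x$drmst_a$drmst, x$drmst_a$ci[1], x$drmst_a$ci[2]))
  for (k in seq_len(nrow(x$km_a$tests))) {
    cat(sprintf("  KM^a log-rank at %g mo: p = %.4g\n",
                x$km_a$tests$horizon[k], x$km_a$tests$p[k]))
  }
  if (!is.null(x$c_index)) {
    cat(sprintf("  C-index RT %.3f / CRT %.3f; IBS RT %.3f / CRT %.3f\n",
                x$c_index["RT"], x$c_index["CRT"], x$ibs["RT"], x$ibs["CRT"]))
  }
  nbad <- sum(!x$smd$balanced)
  cat(sprintf("  covariates with post-IPTW |SMD| >= 0.1: %d of %d\n",
              nbad, nrow(x$smd)))
  invisible(x)
}
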