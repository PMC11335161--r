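#' Odds-ratio explanation of recommendation behavior
#'
#' Fits a logistic regression of the model's recommendation (CRT = 1) on the
#' cohort covariates with a random intercept per reporting region. An odds
#' ratio above 1 means the feature (or a one-unit increase in it) pushes the
#' recommendation toward CRT; below 1, toward RT. When the region variance
#' component is estimated at (near) zero, or the mixed fit fails, the
#' function falls back to a fixed-effects logistic fit with region dummies
#' and records which route was taken. Constant covariates are excluded with
#' a warning, and complete separation triggers a warning with clipped CIs
#' rather than an error.
#'
#' @param cohort Cohort `data.frame` with covariates and a `region` column.
#' @param recommended Recommendations ("RT"/"CRT" or 0/1), aligned with
#'   `cohort` rows.
#' @param conf Confidence level (default 0.95).
#' @return A `data.frame` of class `bsl_or_table`: `term`, `or`, `ci_lower`,
#'   `ci_upper`, `direction`; the estimation route is in `attr(, "method")`.
#' @export
recommendation_or <- function(cohort, recommended, conf = 0.95) {
  assert_cols(cohort, "region")
  y <- if (is.numeric(recommended)) as.integer(recommended) else
    as.integer(as.character(recommended) == "CRT")
  design <- cohort_design(cohort)
  keep <- apply(design, 2, function(v) stats::var(v) > 0)
  if (any(!keep)) {
    warn_bsl("excluding constant covariate(s): %s",
             paste(colnames(design)[!keep], collapse = ", "))
    design <- design[, keep, drop = FALSE]
  }
  df <- data.frame(.y = y, design, .region = factor(cohort$region),
                   check.names = TRUE)
  xnames <- setdiff(names(df), c(".y", ".region"))
  method <- "mixed"
  fit <- tryCatch({
    f <- stats::as.formula(paste(".y ~", paste(xnames, collapse = " + "),
                                 "+ (1 | .region)"))
    m <- suppressWarnings(lme4::glmer(f, data = df, family = stats::binomial(),
                                      nAGQ = 0L))
    vc <- as.data.frame(lme4::VarCorr(m))$vcov[1]
    if (vc < 1e-8) { method <- "fixed (region variance ~ 0)"; NULL } else m
  }, error = function(e) {
    method <<- paste0("fixed (mixed fit failed: ", conditionMessage(e), ")")
    NULL
  })
  if (is.null(fit)) {
    f <- stats::as.formula(paste(".y ~", paste(xnames, collapse = " + "),
                                 "+ .region"))
    fit <- suppressWarnings(stats::glm(f, data = df,
                                       family = stats::binomial()))
    co <- summary(fit)$coefficients
  } else {
    co <- summary(fit)$coefficients
  }
  z <- stats::qnorm(1 - (1 - conf) / 2)
  rows <- intersect(rownames(co), xnames)
  est <- co[rows, "Estimate"]
  se <- co[rows, "Std. Error"]
  if (any(abs(est) > 10) || any(se > 5)) {
    # (near-)complete separation: maximum likelihood diverges, so refit with
    # an L2-penalized logistic model (region as fixed dummies) whose
    # penalized Hessian gives finite Wald intervals
    warn_bsl("complete separation detected; using ridge-penalized fit")
    method <- paste0(method, " + ridge (separation)")
    xr <- cbind(design,
                stats::model.matrix(~ .region, data = df)[, -1, drop = FALSE])
    rf <- ridge_logistic(xr, y, lambda = 1)
    keep_terms <- colnames(design)
    est <- stats::setNames(rf$coef[keep_terms], keep_terms)
    se <- rf$se[keep_terms]
    rows <- keep_terms
  }
  out <- data.frame(
    term = rows,
    or = exp(est),
    ci_lower = exp(est - z * se),
    ci_upper = exp(est + z * se),
    direction = ifelse(est > 0, "toward CRT", "toward RT"),
    row.names = NULL
  )
  attr(out, "method") <- method
  class(out) <- c("bsl_or_table", "data.frame")
  out
}

# L2-penalized logistic regression by Newton iterations; the intercept is
# unpenalized. Standard errors come from the penalized Hessian.
ridge_logistic <- function(x, y, lambda = 1, maxit = 200, tol = 1e-9) {
  xm <- cbind(`(Intercept)` = 1, as.matrix(x))
  p <- ncol(xm)
  pen <- diag(c(0, rep(lambda, p - 1)))
  beta <- numeric(p)
  for (it in seq_len(maxit)) {
    eta <- drop(xm %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    h <- crossprod(xm, xm * w) + pen
    g <- crossprod(xm, y - mu) - pen %*% beta
    step <- solve(h, g)
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  se <- sqrt(diag(solve(h)))
  nm <- colnames(xm)[-1]
  list(coef = stats::setNames(beta[-1], nm),
       se = stats::setNames(se[-1], nm))
}

#' Subgroups recommended for CRT / for RT
#'
#' @param ite ITE table from [compute_ite()].
#' @return Factor with levels `RFC` (recommended for CRT, i.e. `ite > 0`)
#'   and `RFR`; the two partition the table.
#' @export
rfc_rfr <- function(ite) {
  factor(ifelse(ite$recommendation == "CRT", "RFC", "RFR"),
         levels = c("RFC", "RFR"))
}

#' Average treatment effect of CRT within a subgroup
#'
#' Within the selected patients, the hazard ratio of CRT vs RT from a
#' multivariate Cox model (adjusted for the cohort covariates) and an
#' IPTW-adjusted hazard ratio (propensity of CRT from the covariates within
#' the subgroup, stabilized truncated weights, robust variance).
#'
#' @param cohort Cohort `data.frame`.
#' @param subset Logical vector selecting the subgroup (default: everyone).
#' @param label Subgroup label for the report row.
#' @param adjust Adjust the unweighted Cox fit for covariates (default TRUE).
#' @return One-row `data.frame`: `subgroup`, `n`, `hr`, `ci_lower`,
#'   `ci_upper`, `hr_adj`, `ci_adj_lower`, `ci_adj_upper`.
#' @export
subgroup_ate <- function(cohort, subset = rep(TRUE, nrow(cohort)),
                         label = "Overall", adjust = TRUE) {
  sub <- cohort[subset, , drop = FALSE]
  if (!nrow(sub)) stop_bsl("subgroup '%s' is empty", label)
  for (arm in 0:1) {
    if (sum(sub$event[sub$treatment == arm]) == 0) {
      stop_bsl("subgroup '%s': arm %d has no events", label, arm)
    }
  }
  design <- cohort_design(sub)
  keep <- apply(design, 2, function(v) stats::var(v) > 0)
  design <- design[, keep, drop = FALSE]
  grp <- factor(sub$treatment, levels = c(0, 1), labels = c("RT", "CRT"))
  hr <- cox_hr(sub$time, sub$event, grp,
               covariates = if (adjust) design else NULL)
  prop <- estimate_propensity(design, sub$treatment)
  wts <- iptw_weights(prop, sub$treatment)
  hr_a <- cox_hr(sub$time, sub$event, grp, weights = wts)
  data.frame(subgroup = label, n = nrow(sub),
             hr = hr$hr, ci_lower = hr$ci[1], ci_upper = hr$ci[2],
             hr_adj = hr_a$hr, ci_adj_lower = hr_a$ci[1],
             ci_adj_upper = hr_a$ci[2])
}

#' Subgroup ATE table for the standard contrasts
#'
#' Builds the Overall / RFC / RFR / Group A / Group B rows: RFC and RFR come
#' from the sign of the model's ITE, Groups A and B from the ground-truth
#' responsiveness rule (age under 40 with overlapping or midline tumors).
#'
#' @param cohort Test cohort.
#' @param ite ITE table aligned with `cohort` by `id`.
#' @return `data.frame` with one row per subgroup (subgroups whose arms lack
#'   events are skipped with a message).
#' @export
subgroup_ate_table <- function(cohort, ite) {
  ite <- ite[match(cohort$id, ite$id), ]
  rr <- rfc_rfr(ite)
  ab <- cohort_group_labels(cohort)
  subsets <- list(Overall = rep(TRUE, nrow(cohort)),
                  RFC = rr == "RFC", RFR = rr == "RFR",
                  GroupA = ab == "A", GroupB = ab == "B")
  rows <- list()
  for (nm in names(subsets)) {
    rows[[nm]] <- tryCatch(subgroup_ate(cohort, subsets[[nm]], label = nm),
                           error = function(e) {
                             message(sprintf("subgroup %s skipped: %s", nm,
                                             conditionMessage(e)))
                             NULL
                           })
  }
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}
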