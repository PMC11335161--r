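#' Default covariate specification for a synthetic low-grade-glioma cohort
#'
#' Returns the covariate specification used by [simulation_config()] when none
#' is supplied. It emulates the structure of a SEER-style LGG registry extract:
#' age and tumor size as continuous variables; sex, residence and metastasis as
#' binaries; race, marital status, income, histology (3 levels), primary site
#' location (9 levels, including an "overlapping" category), laterality,
#' extension (including a "midline" category) and extent of resection
#' (5 levels) as categoricals. Marginal frequencies are plausible for adult
#' diffuse low-grade glioma but make no claim to reproduce any registry's
#' joint distribution.
#'
#' @return A list of covariate descriptors. Each descriptor is a list with
#'   `name`, `kind` (`"continuous"`, `"binary"` or `"categorical"`) and
#'   distribution parameters: `mean`/`sd`/`lower`/`upper` for continuous,
#'   `levels` (length 2) and `p` (probability of the second level) for binary,
#'   `levels`/`probs` for categorical.
#' @export
lgg_covariate_spec <- function() {
  list(
    list(name = "age", kind = "continuous", mean = 43, sd = 13.5,
         lower = 18, upper = 85),
    list(name = "tumor_size", kind = "continuous", mean = 45, sd = 18,
         lower = 5, upper = 120),
    list(name = "sex", kind = "binary", levels = c("female", "male"), p = 0.55),
    list(name = "race", kind = "categorical",
         levels = c("white", "black", "other"), probs = c(0.85, 0.07, 0.08)),
    list(name = "marital", kind = "categorical",
         levels = c("married", "single", "other"), probs = c(0.58, 0.27, 0.15)),
    list(name = "residence", kind = "binary",
         levels = c("metropolitan", "nonmetropolitan"), p = 0.12),
    list(name = "income", kind = "categorical",
         levels = c("low", "medium", "high"), probs = c(0.2, 0.45, 0.35)),
    list(name = "histology", kind = "categorical",
         levels = c("astrocytoma", "oligoastrocytoma", "oligodendroglioma"),
         probs = c(0.37, 0.18, 0.45)),
    list(name = "location", kind = "categorical",
         levels = c("frontal", "temporal", "parietal", "occipital",
                    "cerebrum_nos", "cerebellum", "brainstem", "ventricle",
                    "overlapping"),
         probs = c(0.36, 0.26, 0.12, 0.03, 0.07, 0.03, 0.03, 0.02, 0.08)),
    list(name = "laterality", kind = "categorical",
         levels = c("left", "right", "other"), probs = c(0.48, 0.46, 0.06)),
    list(name = "extension", kind = "categorical",
         levels = c("confined", "midline", "further"),
         probs = c(0.76, 0.09, 0.15)),
    list(name = "mets", kind = "binary", levels = c("no", "yes"), p = 0.02),
    list(name = "resection", kind = "categorical",
         levels = c("no_surgery", "biopsy", "str", "gtr", "sptr"),
         probs = c(0.14, 0.2, 0.3, 0.28, 0.08))
  )
}

default_propensity_coefficients <- function() {
  # log-odds scale; continuous covariates enter standardized by their spec
  # mean/sd, categorical levels enter as offsets (first level implicitly 0)
  list(
    age = -0.8,
    histology = c(astrocytoma = 0.4, oligoastrocytoma = 0.1,
                  oligodendroglioma = 0),
    resection = c(no_surgery = 0.5, biopsy = 0.3, str = 0.1, gtr = 0,
                  sptr = -0.1),
    extension = c(confined = 0, midline = 0.4, further = 0.3),
    mets = c(no = 0, yes = 0.6)
  )
}

default_prognostic_coefficients <- function() {
  list(
    age = 0.45,
    tumor_size = 0.15,
    histology = c(astrocytoma = 0.35, oligoastrocytoma = 0.1,
                  oligodendroglioma = 0),
    resection = c(no_surgery = 0.35, biopsy = 0.25, str = 0.1, gtr = 0,
                  sptr = -0.05),
    extension = c(confined = 0, midline = 0.3, further = 0.25),
    mets = c(no = 0, yes = 0.9)
  )
}

default_effect_modifiers <- function() {
  # chemoradiotherapy benefit concentrated in young patients with overlapping
  # lesions or midline-crossing tumors; mild harm elsewhere
  list(
    rules = list(
      list(expr = "age < 40 & (location == 'overlapping' | extension == 'midline')",
           log_hr = -0.5)
    ),
    default_log_hr = 0.3
  )
}

#' Configuration for the synthetic cohort generator
#'
#' Bundles and validates everything [simulate_cohort()] needs: cohort size,
#' covariate marginals, confounded treatment assignment (a logistic propensity
#' on the covariates plus a small random region intercept), a proportional
#' hazards outcome model with an exponential baseline, a rule-based map of
#' treatment effect modification, and a target censoring fraction.
#'
#' @param n_patients Number of patients to draw (>= 2).
#' @param covariate_spec Covariate descriptors; see [lgg_covariate_spec()].
#' @param propensity_coefficients Named list of log-odds coefficients for
#'   treatment assignment. Continuous covariates are standardized by their
#'   spec mean/sd before the coefficient is applied; binary/categorical
#'   covariates take a named vector of per-level offsets.
#' @param prognostic_coefficients Same structure, on the log-hazard scale,
#'   shared by both arms (these are the confounders when they overlap with
#'   the propensity).
#' @param baseline_hazard_scale Exponential baseline hazard in 1/months for a
#'   patient with zero prognostic index under radiotherapy alone.
#' @param effect_modifiers List with `rules` (each a list with `expr`, an R
#'   expression over covariate names, and `log_hr`) and `default_log_hr`.
#'   The first matching rule sets the patient's CRT log hazard ratio.
#' @param censoring_rate_target Desired fraction of censored records, in
#'   `[0, 1)`. The exponential censoring rate is solved numerically to hit it.
#' @param treatment_prevalence Target marginal probability of CRT; the
#'   propensity intercept is solved numerically to achieve it.
#' @param region_sd Standard deviation of the per-region random intercept
#'   added to the propensity (regions are drawn uniformly from four reporting
#'   areas).
#' @param seed Integer seed; the generator is fully reproducible given it.
#' @return An object of class `bsl_sim_config`.
#' @export
simulation_config <- function(n_patients,
                              covariate_spec = lgg_covariate_spec(),
                              propensity_coefficients = default_propensity_coefficients(),
                              prognostic_coefficients = default_prognostic_coefficients(),
                              baseline_hazard_scale = 0.004,
                              effect_modifiers = default_effect_modifiers(),
                              censoring_rate_target = 0.7,
                              treatment_prevalence = 0.45,
                              region_sd = 0.15,
                              seed = 1L) {
  if (!is.numeric(n_patients) || length(n_patients) != 1 || n_patients < 2 ||
      n_patients != round(n_patients)) {
    stop_bsl("n_patients must be a single integer >= 2 (got %s)",
             format(n_patients))
  }
  if (censoring_rate_target < 0 || censoring_rate_target >= 1) {
    stop_bsl("censoring_rate_target must lie in [0, 1)")
  }
  if (baseline_hazard_scale <= 0) stop_bsl("baseline_hazard_scale must be > 0")
  cov_names <- vapply(covariate_spec, `[[`, character(1), "name")
  if (anyDuplicated(cov_names)) stop_bsl("duplicate covariate names in spec")
  for (cv in covariate_spec) {
    if (!cv$kind %in% c("continuous", "binary", "categorical")) {
      stop_bsl("covariate '%s' has unknown kind '%s'", cv$name, cv$kind)
    }
    if (cv$kind == "categorical" &&
        abs(sum(cv$probs) - 1) > 1e-8) {
      stop_bsl("covariate '%s': level probabilities must sum to 1", cv$name)
    }
  }
  # every effect-modifier rule must reference declared covariates only
  for (rule in effect_modifiers$rules) {
    vars <- all.vars(parse(text = rule$expr)[[1]])
    unknown <- setdiff(vars, cov_names)
    if (length(unknown)) {
      stop_bsl("effect-modifier rule '%s' references undeclared covariate(s): %s",
               rule$expr, paste(unknown, collapse = ", "))
    }
  }
  for (nm in names(propensity_coefficients)) {
    if (!nm %in% cov_names) {
      stop_bsl("propensity coefficient for undeclared covariate '%s'", nm)
    }
  }
  structure(list(
    n_patients = as.integer(n_patients),
    covariate_spec = covariate_spec,
    propensity_coefficients = propensity_coefficients,
    prognostic_coefficients = prognostic_coefficients,
    baseline_hazard_scale = baseline_hazard_scale,
    effect_modifiers = effect_modifiers,
    censoring_rate_target = censoring_rate_target,
    treatment_prevalence = treatment_prevalence,
    region_sd = region_sd,
    seed = as.integer(seed)
  ), class = "bsl_sim_config")
}

draw_covariates <- function(spec, n) {
  out <- list()
  for (cv in spec) {
    x <- switch(cv$kind,
      continuous = {
        v <- stats::rnorm(n, cv$mean, cv$sd)
        lo <- cv$lower %||% -Inf
        hi <- cv$upper %||% Inf
        pmin(pmax(v, lo), hi)
      },
      binary = factor(
        cv$levels[1 + (stats::runif(n) < cv$p)], levels = cv$levels),
      categorical = factor(
        sample(cv$levels, n, replace = TRUE, prob = cv$probs),
        levels = cv$levels)
    )
    out[[cv$name]] <- x
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

# linear predictor from a coefficient map (continuous standardized by spec)
coef_linear_predictor <- function(df, coefs, spec) {
  spec_by_name <- stats::setNames(spec, vapply(spec, `[[`, character(1), "name"))
  lp <- numeric(nrow(df))
  for (nm in names(coefs)) {
    cv <- spec_by_name[[nm]]
    if (cv$kind == "continuous") {
      lp <- lp + coefs[[nm]] * (df[[nm]] - cv$mean) / cv$sd
    } else {
      offs <- coefs[[nm]]
      miss <- setdiff(levels(df[[nm]]), names(offs))
      if (length(miss)) {
        stop_bsl("coefficient map for '%s' misses level(s): %s", nm,
                 paste(miss, collapse = ", "))
      }
      lp <- lp + unname(offs[as.character(df[[nm]])])
    }
  }
  lp
}

crt_log_hr <- function(df, effect_modifiers) {
  log_hr <- rep(effect_modifiers$default_log_hr, nrow(df))
  unset <- rep(TRUE, nrow(df))
  for (rule in effect_modifiers$rules) {
    hit <- eval(parse(text = rule$expr)[[1]], envir = df)
    hit <- hit & unset
    log_hr[hit] <- rule$log_hr
    unset <- unset & !hit
  }
  log_hr
}

#' Simulate a SEER-like LGG cohort with known ground truth
#'
#' Draws covariates from the configured marginals, assigns radiotherapy (RT,
#' coded 0) or chemoradiotherapy (CRT, coded 1) from a logistic propensity on
#' the covariates with a per-region random intercept, draws brain-cancer death
#' times from an exponential proportional-hazards model whose CRT log hazard
#' ratio follows the effect-modifier rules, and applies independent
#' exponential censoring calibrated to the target censoring fraction. The
#' returned cohort carries each patient's true individual treatment effect
#' (difference of true median survival, CRT minus RT, in months), so every
#' downstream stage has an exact oracle.
#'
#' @param config A [simulation_config()] object.
#' @return A `data.frame` with columns `id`, the covariates, `region`,
#'   `propensity`, `treatment` (0/1), `time` (months, > 0), `event` (0/1),
#'   `true_log_hr` and `true_ite_months`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "bsl_sim_config"))
  with_seed(config$seed, {
    n <- config$n_patients
    df <- draw_covariates(config$covariate_spec, n)

    regions <- c("Midwest", "East", "South", "Oversea")
    region <- factor(sample(regions, n, replace = TRUE), levels = regions)
    region_int <- stats::rnorm(length(regions), 0, config$region_sd)

    lp_treat <- coef_linear_predictor(df, config$propensity_coefficients,
                                      config$covariate_spec) +
      region_int[as.integer(region)]
    # intercept solved so that the marginal CRT fraction hits the target
    b0 <- tryCatch(
      stats::uniroot(function(b) mean(stats::plogis(b + lp_treat)) -
                       config$treatment_prevalence,
                     interval = c(-20, 20))$root,
      error = function(e) stop_bsl(
        "could not calibrate propensity intercept: %s", conditionMessage(e)))
    propensity <- stats::plogis(b0 + lp_treat)
    treatment <- as.integer(stats::runif(n) < propensity)
    if (all(treatment == 1)) stop_bsl(
      "degenerate propensity: the RT arm (treatment = 0) is empty")
    if (all(treatment == 0)) stop_bsl(
      "degenerate propensity: the CRT arm (treatment = 1) is empty")

    lp_prog <- coef_linear_predictor(df, config$prognostic_coefficients,
                                     config$covariate_spec)
    log_hr <- crt_log_hr(df, config$effect_modifiers)
    rate_rt <- config$baseline_hazard_scale * exp(lp_prog)
    rate_crt <- rate_rt * exp(log_hr)
    rate_obs <- ifelse(treatment == 1, rate_crt, rate_rt)

    event_time <- stats::rexp(n, rate_obs)

    # independent exponential censoring; rate solved so the expected censored
    # fraction E[c / (c + rate_i)] matches the target
    target <- config$censoring_rate_target
    if (target > 0) {
      cens_rate <- stats::uniroot(
        function(lc) mean(exp(lc) / (exp(lc) + rate_obs)) - target,
        interval = c(-30, 10), extendInt = "upX")$root
      cens_time <- stats::rexp(n, exp(cens_rate))
      time <- pmin(event_time, cens_time)
      event <- as.integer(event_time <= cens_time)
    } else {
      time <- event_time
      event <- rep(1L, n)
    }

    true_ite <- log(2) / rate_crt - log(2) / rate_rt

    out <- cbind(
      data.frame(id = seq_len(n)),
      df,
      data.frame(region = region,
                 propensity = propensity,
                 treatment = treatment,
                 time = time,
                 event = event,
                 true_log_hr = log_hr,
                 true_ite_months = true_ite)
    )
    attr(out, "sim_config") <- config
    out
  })
}

#' Ground-truth treatment-responsiveness group of a patient
#'
#' Group A collects patients under 40 years of age whose tumor is an
#' overlapping lesion or crosses the midline -- the stratum where combined
#' chemoradiotherapy is beneficial by construction in the default simulator --
#' and Group B is its complement. "Under 40" is read strictly (`age < 40`).
#'
#' @param record A single-row `data.frame` or named list with `age`,
#'   `location` and `extension`.
#' @return `"A"` or `"B"`.
#' @seealso [cohort_group_labels()] for the vectorized form.
#' @export
true_group_label <- function(record) {
  for (nm in c("age", "location", "extension")) {
    if (is.null(record[[nm]]) || length(record[[nm]]) == 0 ||
        is.na(record[[nm]][1])) {
      stop_bsl("true_group_label: missing covariate '%s'", nm)
    }
  }
  age <- as.numeric(record[["age"]][1])
  loc <- as.character(record[["location"]][1])
  ext <- as.character(record[["extension"]][1])
  if (age < 40 && (loc == "overlapping" || ext == "midline")) "A" else "B"
}

#' Vectorized Group A/B labels for a cohort
#'
#' @param cohort A cohort `data.frame` with `age`, `location`, `extension`.
#' @return Character vector of `"A"`/`"B"`, one per row.
#' @export
cohort_group_labels <- function(cohort) {
  assert_cols(cohort, c("age", "location", "extension"))
  ifelse(cohort$age < 40 &
           (as.character(cohort$location) == "overlapping" |
              as.character(cohort$extension) == "midline"),
         "A", "B")
}

#' Write / read a cohort as CSV
#'
#' The file starts with commented header lines documenting the schema (one
#' row per patient; missing values are forbidden), followed by a standard
#' CSV table.
#'
#' @param cohort Cohort `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  if (anyNA(cohort)) stop_bsl("cohort contains missing values")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# bslnet cohort: one row per patient; missing values forbidden",
    "# treatment: 0 = RT, 1 = CRT; time: months > 0; event: 1 = brain-cancer death, 0 = censored",
    paste0("# columns: ", paste(names(cohort), collapse = ","))
  ), con)
  utils::write.table(cohort, con, sep = ",", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = TRUE)
  if (anyNA(df)) stop_bsl("cohort file '%s' contains missing values", path)
  if (!all(df$event %in% c(0, 1))) stop_bsl("event must be 0/1")
  if (!all(df$treatment %in% c(0, 1))) stop_bsl("treatment must be 0/1")
  if (any(df$time <= 0)) stop_bsl("follow-up times must be positive")
  df
}

#' Write / read a simulation configuration as YAML
#'
#' @param config A [simulation_config()].
#' @param path File path.
#' @return `path` (write) or a `bsl_sim_config` (read).
#' @export
write_simulation_config <- function(config, path) {
  stopifnot(inherits(config, "bsl_sim_config"))
  out <- unclass(config)
  # named numeric vectors must become YAML maps or their names are lost
  as_map <- function(cc) lapply(cc, function(v)
    if (!is.null(names(v))) as.list(v) else v)
  out$propensity_coefficients <- as_map(out$propensity_coefficients)
  out$prognostic_coefficients <- as_map(out$prognostic_coefficients)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @rdname write_simulation_config
#' @export
read_simulation_config <- function(path) {
  raw <- yaml::read_yaml(path)
  # yaml flattens named vectors into named lists; restore numeric vectors
  fix_coefs <- function(cc) lapply(cc, function(v) {
    if (is.list(v)) unlist(v) else v
  })
  simulation_config(
    n_patients = raw$n_patients,
    covariate_spec = lapply(raw$covariate_spec, function(cv) {
      cv$levels <- unlist(cv$levels)
      cv$probs <- unlist(cv$probs)
      cv
    }),
    propensity_coefficients = fix_coefs(raw$propensity_coefficients),
    prognostic_coefficients = fix_coefs(raw$prognostic_coefficients),
    baseline_hazard_scale = raw$baseline_hazard_scale,
    effect_modifiers = list(
      rules = lapply(raw$effect_modifiers$rules, function(r)
        list(expr = r$expr, log_hr = r$log_hr)),
      default_log_hr = raw$effect_modifiers$default_log_hr
    ),
    censoring_rate_target = raw$censoring_rate_target,
    treatment_prevalence = raw$treatment_prevalence,
    region_sd = raw$region_sd,
    seed = raw$seed
  )
}
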