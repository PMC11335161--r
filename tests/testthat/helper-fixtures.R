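# Shared fixtures: compact cohorts and models built in code at test time.

# small covariate set so logistic/Cox fits stay fast in tests
compact_covariate_spec <- function() {
  list(
    list(name = "age", kind = "continuous", mean = 43, sd = 13.5,
         lower = 18, upper = 85),
    list(name = "tumor_size", kind = "continuous", mean = 45, sd = 18,
         lower = 5, upper = 120),
    list(name = "sex", kind = "binary", levels = c("female", "male"), p = 0.55),
    list(name = "histology", kind = "categorical",
         levels = c("astrocytoma", "oligoastrocytoma", "oligodendroglioma"),
         probs = c(0.37, 0.18, 0.45)),
    list(name = "location", kind = "categorical",
         levels = c("frontal", "temporal", "overlapping"),
         probs = c(0.55, 0.33, 0.12)),
    list(name = "extension", kind = "categorical",
         levels = c("confined", "midline", "further"),
         probs = c(0.76, 0.12, 0.12))
  )
}

compact_sim_config <- function(n, seed = 1, effect = "hetero",
                               censoring = 0.5, region_sd = 0.1) {
  em <- switch(effect,
    hetero = list(rules = list(list(
      expr = "age < 40 & (location == 'overlapping' | extension == 'midline')",
      log_hr = -0.5)), default_log_hr = 0.3),
    null = list(rules = list(), default_log_hr = 0),
    strong = list(rules = list(list(
      expr = "age < 40 & (location == 'overlapping' | extension == 'midline')",
      log_hr = -1)), default_log_hr = 0.3))
  simulation_config(
    n_patients = n,
    covariate_spec = compact_covariate_spec(),
    propensity_coefficients = list(
      age = -0.8,
      histology = c(astrocytoma = 0.4, oligoastrocytoma = 0.1,
                    oligodendroglioma = 0),
      extension = c(confined = 0, midline = 0.4, further = 0.3)),
    prognostic_coefficients = list(
      age = 0.45,
      histology = c(astrocytoma = 0.35, oligoastrocytoma = 0.1,
                    oligodendroglioma = 0),
      extension = c(confined = 0, midline = 0.3, further = 0.25)),
    baseline_hazard_scale = 0.008,
    effect_modifiers = em,
    censoring_rate_target = censoring,
    region_sd = region_sd,
    seed = seed)
}

tiny_bsl_config <- function(...) {
  args <- utils::modifyList(list(
    shared_layers = c(8L), latent_dim = 4L, head_hidden_layers = c(4L),
    lasso_lambda = 0.001, hierarchy_M = 10, balance_alpha = 0.5,
    ot_epsilon = 0.5, ot_batch = 64L, learning_rate = 0.02,
    patience_iterations = 50L, max_iterations = 120L, seed = 1L), list(...))
  do.call(bsl_config, args)
}

# a model whose every parameter is zero: scores are 0 for any input
zero_model <- function(p = 3, basehaz0 = NULL, basehaz1 = NULL) {
  cfg <- bsl_config(shared_layers = integer(0), latent_dim = 2L,
                    head_hidden_layers = integer(0), balance_alpha = 0,
                    max_iterations = 1L, seed = 1L)
  params <- list(
    sh_W1 = matrix(0, p, 2), sh_b1 = numeric(2),
    h0_theta = numeric(2), h0_W1 = matrix(0, 2, 1), h0_b1 = numeric(1),
    h1_theta = numeric(2), h1_W1 = matrix(0, 2, 1), h1_b1 = numeric(1))
  structure(list(params = params, config = cfg, n_features = p,
                 feature_names = paste0("x", seq_len(p)),
                 history = NULL, best_iter = 1L,
                 baselines = list(basehaz0, basehaz1), horizon = 120),
            class = "bsl_model")
}

make_basehaz <- function(time, hazard) {
  structure(list(time = time, hazard = hazard), class = "bsl_basehaz")
}

# linear proportional-hazards data for per-arm recovery checks
linear_cox_data <- function(n, p = 4, beta0 = c(1, -1, 0.5, 0),
                            beta1 = c(-0.5, 1, 0, 0.5), seed = 1,
                            base_rate = 0.01, admin_cens = NULL) {
  withr_seed <- function(expr) { set.seed(seed); expr }
  withr_seed({
    x <- matrix(rnorm(n * p), n, p)
    treatment <- rbinom(n, 1, 0.5)
    lp <- ifelse(treatment == 1, x %*% beta1, x %*% beta0)
    t_ev <- rexp(n, base_rate * exp(lp))
    cens <- admin_cens %||% stats::quantile(t_ev, 0.8)
    time <- pmin(t_ev, cens)
    event <- as.integer(t_ev <= cens)
    list(x = x, time = time, event = event, treatment = treatment,
         lp = as.numeric(lp))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
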