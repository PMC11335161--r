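#' Save / load a fitted model as a single JSON checkpoint
#'
#' The checkpoint stores the architecture (config), flat parameter arrays
#' with their dimensions, feature names, per-arm baseline hazards and the
#' prediction horizon, so a model restored with [read_bsl()] reproduces
#' predictions exactly.
#'
#' @param model A fitted `bsl_model`.
#' @param path Output path (JSON).
#' @return `path` (write) or the restored `bsl_model` (read).
#' @export
write_bsl <- function(model, path) {
  stopifnot(inherits(model, "bsl_model"))
  flat <- lapply(model$params, function(p) {
    list(dim = if (is.matrix(p)) dim(p) else length(p), data = as.numeric(p))
  })
  payload <- list(
    format = "bslnet-checkpoint-1",
    config = unclass(model$config),
    n_features = model$n_features,
    feature_names = model$feature_names,
    params = flat,
    baselines = list(
      arm0 = list(time = model$baselines[[1]]$time,
                  hazard = model$baselines[[1]]$hazard),
      arm1 = list(time = model$baselines[[2]]$time,
                  hazard = model$baselines[[2]]$hazard)),
    horizon = model$horizon,
    best_iter = model$best_iter
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_bsl
#' @export
read_bsl <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(raw$format, "bslnet-checkpoint-1")) {
    stop_bsl("'%s' is not a bslnet checkpoint", path)
  }
  cfg <- raw$config
  config <- bsl_config(
    shared_layers = cfg$shared_layers, latent_dim = cfg$latent_dim,
    head_hidden_layers = cfg$head_hidden_layers,
    lasso_lambda = cfg$lasso_lambda, hierarchy_M = cfg$hierarchy_M,
    balance_alpha = cfg$balance_alpha, ot_epsilon = cfg$ot_epsilon,
    ot_batch = cfg$ot_batch, learning_rate = cfg$learning_rate,
    batch_size = cfg$batch_size, patience_iterations = cfg$patience_iterations,
    max_iterations = cfg$max_iterations, dropout_rate = cfg$dropout_rate,
    ties = cfg$ties, skip_on = cfg$skip_on, seed = cfg$seed)
  params <- lapply(raw$params, function(p) {
    if (length(p$dim) == 2) matrix(p$data, p$dim[1], p$dim[2])
    else as.numeric(p$data)
  })
  baselines <- lapply(c("arm0", "arm1"), function(nm)
    structure(list(time = as.numeric(raw$baselines[[nm]]$time),
                   hazard = as.numeric(raw$baselines[[nm]]$hazard)),
              class = "bsl_basehaz"))
  structure(list(
    params = params, config = config, n_features = raw$n_features,
    feature_names = raw$feature_names,
    history = NULL, best_iter = raw$best_iter,
    baselines = baselines, horizon = raw$horizon
  ), class = "bsl_model")
}
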