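#' Default run configuration for the end-to-end pipeline
#'
#' @param out_dir Output directory for all artifacts.
#' @param seed Global seed; propagated to every stage.
#' @param n_patients Cohort size when simulating.
#' @param cohort_path Optional path to an existing cohort CSV (skips
#'   simulation).
#' @param test_fraction Held-out fraction for evaluation.
#' @param sim Named overrides for [simulation_config()].
#' @param model Named overrides for [bsl_config()].
#' @param tune_grid Optional hyperparameter grid for CV tuning.
#' @param stages Named logical toggles: `simulate`, `train`, `recommend`,
#'   `evaluate`, `interpret`.
#' @param tau,horizons Evaluation horizons (months).
#' @param log_level `"info"` or `"quiet"`.
#' @return A list of class `bsl_run_config`.
#' @export
run_config <- function(out_dir, seed = 1L, n_patients = 1000L,
                       cohort_path = NULL, test_fraction = 0.2,
                       sim = list(), model = list(), tune_grid = NULL,
                       stages = list(), tau = 60, horizons = c(60, 120),
                       log_level = "info") {
  st <- utils::modifyList(list(simulate = is.null(cohort_path), train = TRUE,
                               recommend = TRUE, evaluate = TRUE,
                               interpret = TRUE), stages)
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 n_patients = as.integer(n_patients),
                 cohort_path = cohort_path, test_fraction = test_fraction,
                 sim = sim, model = model, tune_grid = tune_grid,
                 stages = st, tau = tau, horizons = horizons,
                 log_level = log_level), class = "bsl_run_config")
}

validate_run_config <- function(config) {
  if (!inherits(config, "bsl_run_config")) stop_bsl("not a bsl_run_config")
  st <- config$stages
  if (!st$simulate && is.null(config$cohort_path)) {
    stop_bsl("configuration error: no cohort source (simulate disabled and no cohort_path)")
  }
  if (!st$simulate && !is.null(config$cohort_path) &&
      !file.exists(config$cohort_path)) {
    stop_bsl("configuration error: cohort_path '%s' does not exist",
             config$cohort_path)
  }
  if ((st$evaluate || st$recommend) &&
      (is.null(config$test_fraction) || config$test_fraction <= 0 ||
         config$test_fraction >= 1)) {
    stop_bsl("configuration error: evaluation requires a test split (test_fraction in (0,1))")
  }
  if (st$evaluate && !st$recommend) {
    stop_bsl("configuration error: evaluate requires the recommend stage")
  }
  if ((st$recommend || st$evaluate) && !st$train) {
    stop_bsl("configuration error: recommend/evaluate require the train stage")
  }
  invisible(TRUE)
}

run_log <- function(config, fmt, ...) {
  if (identical(config$log_level, "info")) {
    message(sprintf(paste0("[bslnet] ", fmt), ...))
  }
}

#' Run the full pipeline: simulate, preprocess, train, recommend, evaluate,
#' interpret
#'
#' Executes the enabled stages in order, writing every artifact to
#' `config$out_dir` as plain text (CSV/JSON) together with a manifest listing
#' each file with its MD5 checksum, the seed and a hash of the
#' configuration. Re-running with the same configuration reproduces the
#' deterministic artifacts byte-identically. Any stage failure aborts with a
#' message naming the stage.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the in-memory objects (`cohort`, `split`,
#'   `model`, `ite`, `report`, `or_table`, `subgroups`) and `paths` of the
#'   written artifacts.
#' @export
run_experiment <- function(config) {
  validate_run_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  result <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_bsl("stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  # --- cohort ---------------------------------------------------------------
  cohort <- stage("simulate", {
    if (config$stages$simulate) {
      sim_args <- utils::modifyList(list(n_patients = config$n_patients,
                                         seed = config$seed), config$sim)
      sim_cfg <- do.call(simulation_config, sim_args)
      run_log(config, "simulating cohort (n = %d)", sim_cfg$n_patients)
      co <- simulate_cohort(sim_cfg)
      paths$cohort <- file.path(config$out_dir, "cohort.csv")
      write_cohort(co, paths$cohort)
      co
    } else {
      run_log(config, "reading cohort from %s", config$cohort_path)
      read_cohort(config$cohort_path)
    }
  })
  result$cohort <- cohort

  # --- preprocess -----------------------------------------------------------
  split <- stage("preprocess", {
    sp <- split_cohort(cohort, test_fraction = config$test_fraction,
                       seed = config$seed)
    paths$split <- file.path(config$out_dir, "split.csv")
    write_split(sp, paths$split)
    sp
  })
  result$split <- split
  enc <- stage("preprocess", encode_features(cohort, fit_on = split$train_ids))
  tr_rows <- which(cohort$id %in% split$train_ids)
  te_rows <- which(cohort$id %in% split$test_ids)

  if (!config$stages$train) {
    return(invisible(finish_run(config, result, paths)))
  }

  # --- train ----------------------------------------------------------------
  model <- stage("train", {
    mdl_args <- utils::modifyList(list(seed = config$seed), config$model)
    bcfg <- do.call(bsl_config, mdl_args)
    folds <- make_cv_folds(seq_along(tr_rows), k = 5L, seed = config$seed)
    run_log(config, "training BSL (%d train rows)", length(tr_rows))
    m <- train_bsl(enc$x[tr_rows, , drop = FALSE], cohort$time[tr_rows],
                   cohort$event[tr_rows], cohort$treatment[tr_rows],
                   config = bcfg,
                   folds = if (!is.null(config$tune_grid)) folds else NULL,
                   tune_grid = config$tune_grid)
    paths$model <- file.path(config$out_dir, "model.json")
    write_bsl(m, paths$model)
    paths$history <- file.path(config$out_dir, "history.csv")
    utils::write.csv(m$history, paths$history, row.names = FALSE)
    m
  })
  result$model <- model

  # --- recommend ------------------------------------------------------------
  if (config$stages$recommend) {
    ite <- stage("recommend", {
      run_log(config, "computing ITE for %d test patients", length(te_rows))
      it <- compute_ite(model, enc$x[te_rows, , drop = FALSE],
                        ids = cohort$id[te_rows])
      paths$ite <- file.path(config$out_dir, "ite.csv")
      write_ite(it, paths$ite)
      it
    })
    result$ite <- ite
  }

  # --- evaluate -------------------------------------------------------------
  if (config$stages$evaluate) {
    report <- stage("evaluate", {
      test_cohort <- cohort[te_rows, , drop = FALSE]
      rep <- evaluate_recommendations(test_cohort, result$ite, model = model,
                                      x = enc$x[te_rows, , drop = FALSE],
                                      tau = config$tau,
                                      horizons = config$horizons)
      paths$evaluation <- file.path(config$out_dir, "evaluation.json")
      jsonlite::write_json(list(
        n = nrow(test_cohort), n_rec = rep$n_rec,
        hr = rep$hr$hr, hr_ci = rep$hr$ci,
        hr_cov = rep$hr_cov$hr, hr_cov_ci = rep$hr_cov$ci,
        hr_a = rep$hr_a$hr, hr_a_ci = rep$hr_a$ci,
        drmst = rep$drmst$drmst, drmst_ci = rep$drmst$ci,
        drmst_a = rep$drmst_a$drmst, drmst_a_ci = rep$drmst_a$ci,
        logrank = rep$km$tests, logrank_weighted = rep$km_a$tests,
        c_index = as.list(rep$c_index), ibs = as.list(rep$ibs),
        max_abs_smd_weighted = max(abs(rep$smd$smd_weighted)),
        tau = rep$tau
      ), paths$evaluation, auto_unbox = TRUE, digits = NA)
      paths$smd <- file.path(config$out_dir, "smd.csv")
      utils::write.csv(rep$smd, paths$smd, row.names = FALSE)
      paths$km <- file.path(config$out_dir, "km_weighted.csv")
      utils::write.csv(rep$km_a$curves, paths$km, row.names = FALSE)
      rep
    })
    result$report <- report
  }

  # --- interpret ------------------------------------------------------------
  if (config$stages$interpret && config$stages$recommend) {
    stage("interpret", {
      tr_cohort <- cohort[tr_rows, , drop = FALSE]
      ite_tr <- compute_ite(model, enc$x[tr_rows, , drop = FALSE],
                            ids = cohort$id[tr_rows])
      if (length(unique(ite_tr$recommendation)) == 2 &&
          "region" %in% names(tr_cohort)) {
        ort <- recommendation_or(tr_cohort, ite_tr$recommendation)
        paths$or_table <- file.path(config$out_dir, "or_table.csv")
        utils::write.csv(as.data.frame(ort), paths$or_table, row.names = FALSE)
        result$or_table <- ort
      } else {
        run_log(config, "interpret: recommendations are one-sided; OR table skipped")
      }
      test_cohort <- cohort[te_rows, , drop = FALSE]
      sg <- subgroup_ate_table(test_cohort, result$ite)
      paths$subgroups <- file.path(config$out_dir, "subgroup_ate.csv")
      utils::write.csv(sg, paths$subgroups, row.names = FALSE)
      result$subgroups <- sg
    })
  }

  invisible(finish_run(config, result, paths))
}

finish_run <- function(config, result, paths) {
  files <- unlist(paths)
  cfg_file <- tempfile()
  writeLines(paste(utils::capture.output(utils::str(
    config[setdiff(names(config), "out_dir")])), collapse = "\n"), cfg_file)
  manifest <- list(
    seed = config$seed,
    config_hash = unname(tools::md5sum(cfg_file)),
    files = lapply(stats::setNames(as.list(files), names(paths)), function(f)
      list(path = basename(f), md5 = unname(tools::md5sum(f))))
  )
  unlink(cfg_file)
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE)
  result$paths <- c(paths, manifest = manifest_path)
  result
}

#' Read a run configuration from YAML
#' @param path YAML file with the fields of [run_config()].
#' @param ... Overrides applied after reading.
#' @return A `bsl_run_config`.
#' @export
read_run_config <- function(path, ...) {
  raw <- yaml::read_yaml(path)
  over <- list(...)
  for (nm in names(over)) raw[[nm]] <- over[[nm]]
  do.call(run_config, raw)
}
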