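#' Configuration of the Balanced Survival Lasso-Network
#'
#' The model couples a shared representation network with two
#' treatment-specific risk heads trained on the Cox partial likelihood. The
#' shared network is balanced across arms by a Sinkhorn (smoothed optimal
#' transport) divergence between the arms' latent clouds, weighted by
#' `balance_alpha`. Each head is a LassoNet: a linear skip connection with an
#' L1 penalty `lasso_lambda` plus a small multilayer perceptron whose
#' first-layer rows are bounded by `hierarchy_M` times the corresponding skip
#' weight, enforced after every optimizer step by [hier_prox()]. Setting
#' `lasso_lambda = 0` and `hierarchy_M = Inf` recovers the balanced twin-head
#' deep Cox model without feature selection; `balance_alpha = 0` disables
#' balancing.
#'
#' @param shared_layers Integer widths of the shared hidden layers.
#' @param latent_dim Width of the shared (latent) representation.
#' @param head_hidden_layers Integer widths of each risk head's hidden
#'   layers; `integer(0)` gives a linear head.
#' @param lasso_lambda L1 penalty on each head's linear skip weights (>= 0).
#' @param hierarchy_M Bound linking first-layer rows to skip weights (> 0,
#'   `Inf` allowed).
#' @param balance_alpha Weight of the optimal-transport balancing term (>= 0).
#' @param ot_epsilon Entropic blur of the Sinkhorn divergence (> 0).
#' @param ot_batch Maximum points per arm entering the balancing term each
#'   iteration (the term is estimated on a subsample for speed).
#' @param learning_rate Adam step size.
#' @param batch_size Minibatch size, or `NULL` for full-batch training
#'   (batches are stratified so both arms are always represented).
#' @param patience_iterations Early stopping patience: training halts when
#'   the validation loss has not decreased for this many consecutive
#'   iterations. Default 1000.
#' @param max_iterations Hard cap on optimizer iterations.
#' @param dropout_rate Dropout rate in the shared hidden layers (training
#'   only).
#' @param ties Tie handling for the partial likelihood, `"breslow"` or
#'   `"efron"`.
#' @param skip_on `"latent"` (default): the skip connection acts on the
#'   shared representation, so the hierarchy couples it with the head's first
#'   layer. `"raw"`: the skip acts on the raw features; the hierarchy cannot
#'   couple dimensions of different spaces, so the skip then receives a plain
#'   soft-threshold.
#' @param seed Integer seed for initialization and batching.
#' @return Object of class `bsl_config`.
#' @export
bsl_config <- function(shared_layers = c(16L, 16L),
                       latent_dim = 8L,
                       head_hidden_layers = c(8L),
                       lasso_lambda = 0.001,
                       hierarchy_M = 10,
                       balance_alpha = 1,
                       ot_epsilon = 0.5,
                       ot_batch = 128L,
                       learning_rate = 0.01,
                       batch_size = NULL,
                       patience_iterations = 1000L,
                       max_iterations = 5000L,
                       dropout_rate = 0,
                       ties = "breslow",
                       skip_on = c("latent", "raw"),
                       seed = 1L) {
  skip_on <- match.arg(skip_on)
  if (lasso_lambda < 0) stop_bsl("lasso_lambda must be >= 0")
  if (hierarchy_M <= 0) stop_bsl("hierarchy_M must be > 0")
  if (balance_alpha < 0) stop_bsl("balance_alpha must be >= 0")
  if (ot_epsilon <= 0) stop_bsl("ot_epsilon must be > 0")
  if (latent_dim < 1) stop_bsl("latent_dim must be >= 1")
  if (dropout_rate < 0 || dropout_rate >= 1) stop_bsl("dropout_rate in [0,1)")
  structure(list(
    shared_layers = as.integer(shared_layers),
    latent_dim = as.integer(latent_dim),
    head_hidden_layers = as.integer(head_hidden_layers),
    lasso_lambda = lasso_lambda,
    hierarchy_M = hierarchy_M,
    balance_alpha = balance_alpha,
    ot_epsilon = ot_epsilon,
    ot_batch = as.integer(ot_batch),
    learning_rate = learning_rate,
    batch_size = if (is.null(batch_size)) NULL else as.integer(batch_size),
    patience_iterations = as.integer(patience_iterations),
    max_iterations = as.integer(max_iterations),
    dropout_rate = dropout_rate,
    ties = ties,
    skip_on = skip_on,
    seed = as.integer(seed)
  ), class = "bsl_config")
}

# ---- parameter plumbing -----------------------------------------------------

shared_dims <- function(config, p) c(p, config$shared_layers, config$latent_dim)
head_dims <- function(config, p) {
  d_in <- if (config$skip_on == "latent") config$latent_dim else config$latent_dim
  c(d_in, config$head_hidden_layers, 1L)
}
skip_dim <- function(config, p) {
  if (config$skip_on == "latent") config$latent_dim else p
}

init_params <- function(config, p) {
  he <- function(n_in, n_out) matrix(stats::rnorm(n_in * n_out, 0,
                                                  sqrt(2 / n_in)), n_in, n_out)
  params <- list()
  sd_ <- shared_dims(config, p)
  for (l in seq_len(length(sd_) - 1)) {
    params[[paste0("sh_W", l)]] <- he(sd_[l], sd_[l + 1])
    params[[paste0("sh_b", l)]] <- numeric(sd_[l + 1])
  }
  hd <- head_dims(config, p)
  for (arm in 0:1) {
    pre <- paste0("h", arm, "_")
    params[[paste0(pre, "theta")]] <-
      stats::rnorm(skip_dim(config, p), 0, 1 / sqrt(skip_dim(config, p)))
    for (l in seq_len(length(hd) - 1)) {
      params[[paste0(pre, "W", l)]] <- he(hd[l], hd[l + 1])
      params[[paste0(pre, "b", l)]] <- numeric(hd[l + 1])
    }
  }
  # make the LassoNet constraint feasible at initialization
  for (arm in 0:1) params <- apply_hier_prox(params, config, arm, 0, 1)
  params
}

apply_hier_prox <- function(params, config, arm, lambda, step) {
  pre <- paste0("h", arm, "_")
  if (config$skip_on == "latent") {
    pr <- hier_prox(params[[paste0(pre, "theta")]],
                    params[[paste0(pre, "W1")]],
                    lambda, config$hierarchy_M, step)
    params[[paste0(pre, "theta")]] <- pr$theta
    params[[paste0(pre, "W1")]] <- pr$w
  } else {
    th <- params[[paste0(pre, "theta")]]
    thr <- lambda * step
    params[[paste0(pre, "theta")]] <- sign(th) * pmax(abs(th) - thr, 0)
  }
  params
}

# ---- forward / backward -----------------------------------------------------

forward_shared <- function(params, config, x, dropout = 0, masks = NULL) {
  n_lay <- length(shared_dims(config, ncol(x))) - 1
  acts <- vector("list", n_lay + 1)
  acts[[1]] <- x
  used_masks <- vector("list", n_lay)
  a <- x
  for (l in seq_len(n_lay)) {
    a <- sweep(a %*% params[[paste0("sh_W", l)]], 2,
               params[[paste0("sh_b", l)]], "+")
    if (l < n_lay) {
      a <- pmax(a, 0)
      if (dropout > 0) {
        mk <- masks[[l]] %||%
          matrix(stats::runif(length(a)) >= dropout, nrow(a), ncol(a))
        a <- a * mk / (1 - dropout)
        used_masks[[l]] <- mk
      }
    }
    acts[[l + 1]] <- a
  }
  list(z = a, acts = acts, masks = used_masks)
}

backward_shared <- function(params, config, cache, dz, dropout = 0) {
  n_lay <- length(cache$acts) - 1
  grads <- list()
  delta <- dz
  for (l in rev(seq_len(n_lay))) {
    a_prev <- cache$acts[[l]]
    grads[[paste0("sh_W", l)]] <- crossprod(a_prev, delta)
    grads[[paste0("sh_b", l)]] <- colSums(delta)
    if (l > 1) {
      delta <- delta %*% t(params[[paste0("sh_W", l)]])
      a_mid <- cache$acts[[l]]
      # undo dropout scaling and kill gradients of dropped/negative units
      if (dropout > 0 && !is.null(cache$masks[[l - 1]])) {
        delta <- delta * cache$masks[[l - 1]] / (1 - dropout)
      }
      delta <- delta * (a_mid > 0)
    }
  }
  grads
}

forward_head <- function(params, config, arm, z, x_raw = NULL) {
  pre <- paste0("h", arm, "_")
  n_lay <- length(head_dims(config, 0)) - 1
  acts <- vector("list", n_lay + 1)
  acts[[1]] <- z
  a <- z
  for (l in seq_len(n_lay)) {
    a <- sweep(a %*% params[[paste0(pre, "W", l)]], 2,
               params[[paste0(pre, "b", l)]], "+")
    if (l < n_lay) a <- pmax(a, 0)
    acts[[l + 1]] <- a
  }
  skip_in <- if (config$skip_on == "latent") z else x_raw
  score <- drop(a) + drop(skip_in %*% params[[paste0(pre, "theta")]])
  list(score = score, acts = acts, skip_in = skip_in)
}

backward_head <- function(params, config, arm, cache, dscore) {
  pre <- paste0("h", arm, "_")
  n_lay <- length(cache$acts) - 1
  grads <- list()
  grads[[paste0(pre, "theta")]] <- drop(crossprod(cache$skip_in, dscore))
  dz_skip <- outer(dscore, params[[paste0(pre, "theta")]])
  delta <- matrix(dscore, ncol = 1)
  for (l in rev(seq_len(n_lay))) {
    a_prev <- cache$acts[[l]]
    grads[[paste0(pre, "W", l)]] <- crossprod(a_prev, delta)
    grads[[paste0(pre, "b", l)]] <- colSums(delta)
    if (l > 1) {
      delta <- delta %*% t(params[[paste0(pre, "W", l)]])
      delta <- delta * (cache$acts[[l]] > 0)
    }
  }
  dz_mlp <- delta %*% t(params[[paste0(pre, "W1")]])
  dz <- dz_mlp
  if (config$skip_on == "latent") dz <- dz + dz_skip
  list(grads = grads, dz = dz,
       dx_skip = if (config$skip_on == "raw") dz_skip else NULL)
}

# ---- loss on a data slice ---------------------------------------------------

bsl_loss <- function(params, config, x, time, event, treatment,
                     ot_idx0 = NULL, ot_idx1 = NULL) {
  fs <- forward_shared(params, config, x, dropout = 0)
  z <- fs$z
  i0 <- which(treatment == 0); i1 <- which(treatment == 1)
  s0 <- forward_head(params, config, 0, z[i0, , drop = FALSE],
                     x[i0, , drop = FALSE])$score
  s1 <- forward_head(params, config, 1, z[i1, , drop = FALSE],
                     x[i1, , drop = FALSE])$score
  nll <- cox_partial_nll(s0, time[i0], event[i0], ties = config$ties) +
    cox_partial_nll(s1, time[i1], event[i1], ties = config$ties)
  ot <- 0
  if (config$balance_alpha > 0) {
    j0 <- ot_idx0 %||% i0[seq_len(min(length(i0), config$ot_batch))]
    j1 <- ot_idx1 %||% i1[seq_len(min(length(i1), config$ot_batch))]
    ot <- ot_balance_loss(z[j0, , drop = FALSE], z[j1, , drop = FALSE],
                          config$ot_epsilon)
  }
  list(total = nll + config$balance_alpha * ot, cox = nll, ot = ot)
}

# ---- Adam -------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

adam_step <- function(params, grads, state, lr,
                      b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    mhat <- state$m[[nm]] / (1 - b1^state$t)
    vhat <- state$v[[nm]] / (1 - b2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# ---- training ---------------------------------------------------------------

#' Fit a Balanced Survival Lasso-Network
#'
#' Minimizes the sum of the two arms' mean negative Cox partial
#' log-likelihoods plus `balance_alpha` times the Sinkhorn divergence between
#' the arms' latent representations, by Adam with the hierarchical proximal
#' operator applied to each head after every step. When validation data is
#' supplied, training stops once the validation loss has not decreased for
#' `patience_iterations` consecutive iterations and the best-validation
#' parameters are restored. Treatment-specific Breslow baseline hazards are
#' estimated on the training data after fitting.
#'
#' @param x Encoded feature matrix (training rows).
#' @param time,event,treatment Outcome vectors aligned with `x`.
#' @param config A [bsl_config()].
#' @param validation Optional list with `x`, `time`, `event`, `treatment`
#'   used for early stopping.
#' @param verbose Print progress every 100 iterations.
#' @return Object of class `bsl_model`: parameters, config, training
#'   `history` (iteration, train and validation loss), `best_iter`,
#'   per-arm `baselines`, and the default prediction `horizon` (99th
#'   percentile of training follow-up).
#' @export
bsl_fit <- function(x, time, event, treatment, config,
                    validation = NULL, verbose = FALSE) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (length(unique(treatment)) < 2) {
    stop_bsl("both treatment arms must be present in the training data")
  }
  for (arm in 0:1) {
    if (sum(event[treatment == arm]) == 0) {
      stop_bsl("arm %d has no events; the partial likelihood is undefined", arm)
    }
  }
  with_seed(config$seed, {
    params <- init_params(config, ncol(x))
    state <- adam_init(params)
    full_batch <- is.null(config$batch_size) || config$batch_size >= n
    idx_arm <- split(seq_len(n), treatment)

    best_val <- Inf; best_iter <- 0L; best_params <- params
    hist_iter <- integer(0); hist_train <- numeric(0); hist_val <- numeric(0)
    have_val <- !is.null(validation)

    for (iter in seq_len(config$max_iterations)) {
      if (full_batch) {
        bidx <- seq_len(n)
      } else {
        # stratified batch: both arms represented proportionally, >= 2 each
        per <- pmax(2, round(config$batch_size *
                               lengths(idx_arm) / n))
        bidx <- c(sample(idx_arm[["0"]], min(per[["0"]], length(idx_arm[["0"]]))),
                  sample(idx_arm[["1"]], min(per[["1"]], length(idx_arm[["1"]]))))
      }
      xb <- x[bidx, , drop = FALSE]
      tb <- time[bidx]; eb <- event[bidx]; trb <- treatment[bidx]

      fs <- forward_shared(params, config, xb, config$dropout_rate)
      z <- fs$z
      i0 <- which(trb == 0); i1 <- which(trb == 1)
      h0 <- forward_head(params, config, 0, z[i0, , drop = FALSE],
                         xb[i0, , drop = FALSE])
      h1 <- forward_head(params, config, 1, z[i1, , drop = FALSE],
                         xb[i1, , drop = FALSE])
      nll0 <- cox_partial_nll(h0$score, tb[i0], eb[i0], ties = config$ties)
      nll1 <- cox_partial_nll(h1$score, tb[i1], eb[i1], ties = config$ties)
      g0 <- cox_nll_grad(h0$score, tb[i0], eb[i0])
      g1 <- cox_nll_grad(h1$score, tb[i1], eb[i1])

      ot_val <- 0
      dz <- matrix(0, nrow(z), ncol(z))
      if (config$balance_alpha > 0 && length(i0) && length(i1)) {
        j0 <- if (length(i0) > config$ot_batch)
          sample(i0, config$ot_batch) else i0
        j1 <- if (length(i1) > config$ot_batch)
          sample(i1, config$ot_batch) else i1
        og <- ot_balance_grad(z[j0, , drop = FALSE], z[j1, , drop = FALSE],
                              config$ot_epsilon)
        ot_val <- og$value
        dz[j0, ] <- dz[j0, ] + config$balance_alpha * og$grad0
        dz[j1, ] <- dz[j1, ] + config$balance_alpha * og$grad1
      }
      train_loss <- nll0 + nll1 + config$balance_alpha * ot_val
      if (!is.finite(train_loss)) {
        stop_bsl(paste0("training diverged at iteration %d ",
                        "(cox0 = %.4g, cox1 = %.4g, ot = %.4g)"),
                 iter, nll0, nll1, ot_val)
      }

      bh0 <- backward_head(params, config, 0, h0, g0)
      bh1 <- backward_head(params, config, 1, h1, g1)
      dz[i0, ] <- dz[i0, ] + bh0$dz
      dz[i1, ] <- dz[i1, ] + bh1$dz
      grads <- c(bh0$grads, bh1$grads,
                 backward_shared(params, config, fs, dz,
                                 config$dropout_rate))

      upd <- adam_step(params, grads, state, config$learning_rate)
      params <- upd$params; state <- upd$state
      for (arm in 0:1) {
        params <- apply_hier_prox(params, config, arm, config$lasso_lambda,
                                  config$learning_rate)
      }

      val_loss <- NA_real_
      if (have_val) {
        val_loss <- bsl_loss(params, config, validation$x, validation$time,
                             validation$event, validation$treatment)$total
        if (val_loss < best_val) {
          best_val <- val_loss; best_iter <- iter; best_params <- params
        } else if (iter - best_iter >= config$patience_iterations) {
          hist_iter <- c(hist_iter, iter)
          hist_train <- c(hist_train, train_loss)
          hist_val <- c(hist_val, val_loss)
          break
        }
        if (best_iter == 0L) { best_iter <- iter; best_params <- params }
      }
      hist_iter <- c(hist_iter, iter)
      hist_train <- c(hist_train, train_loss)
      hist_val <- c(hist_val, val_loss)
      if (verbose && iter %% 100 == 0) {
        message(sprintf("iter %d: train %.4f val %.4f", iter, train_loss,
                        val_loss))
      }
    }
    if (have_val) params <- best_params

    model <- structure(list(
      params = params,
      config = config,
      n_features = ncol(x),
      feature_names = colnames(x),
      history = data.frame(iteration = hist_iter, train_loss = hist_train,
                           validation_loss = hist_val),
      best_iter = if (have_val) best_iter else length(hist_iter),
      baselines = NULL,
      horizon = as.numeric(stats::quantile(time, 0.99))
    ), class = "bsl_model")
    estimate_baselines(model, x, time, event, treatment)
  })
}

#' Risk scores of the fitted model for one arm
#'
#' The counterfactual risk score `head_arm(shared(x)) + theta_arm' z`:
#' evaluating both arms on the same patient yields the factual and
#' counterfactual predictions.
#'
#' @param model A fitted `bsl_model`.
#' @param x Encoded feature matrix (training feature order).
#' @param arm 0 (RT) or 1 (CRT).
#' @return Numeric vector of risk scores (higher = worse prognosis).
#' @export
bsl_forward <- function(model, x, arm) {
  p <- model$n_features
  if (is.null(dim(x))) x <- matrix(as.numeric(x), ncol = p)
  x <- as.matrix(x)
  if (ncol(x) != p) {
    stop_bsl("x has %d columns; model was trained on %d features",
             ncol(x), p)
  }
  if (!arm %in% c(0, 1)) stop_bsl("arm must be 0 or 1")
  z <- forward_shared(model$params, model$config, x, dropout = 0)$z
  forward_head(model$params, model$config, arm, z, x)$score
}

#' Shared latent representation of patients
#' @inheritParams bsl_forward
#' @return Matrix of latent coordinates, one row per patient.
#' @export
bsl_latent <- function(model, x) {
  forward_shared(model$params, model$config, as.matrix(x), dropout = 0)$z
}

#' Estimate treatment-specific Breslow baseline hazards
#'
#' Each arm's cumulative baseline hazard is estimated from that arm's
#' training subjects and the model's fitted scores, via [breslow_baseline()].
#' [bsl_fit()] calls this automatically; call it directly to re-anchor the
#' baselines on other data.
#'
#' @param model A `bsl_model`.
#' @param x,time,event,treatment Training data.
#' @return The model with `baselines` filled (list: arm 0, arm 1).
#' @export
estimate_baselines <- function(model, x, time, event, treatment) {
  x <- as.matrix(x)
  bl <- list()
  for (arm in 0:1) {
    idx <- which(treatment == arm)
    if (!length(idx)) stop_bsl("arm %d has no subjects", arm)
    sc <- bsl_forward(model, x[idx, , drop = FALSE], arm)
    bl[[arm + 1]] <- breslow_baseline(sc, time[idx], event[idx])
  }
  model$baselines <- bl
  model
}

#' Train a BSL model with optional cross-validated hyperparameter tuning
#'
#' When `tune_grid` and `folds` are supplied, every combination in the grid
#' is scored by k-fold cross-validation (mean best validation loss across
#' folds) and the winning configuration is refitted. The final fit holds out
#' `val_fraction` of the training rows (stratified on arm and event status)
#' as the early-stopping validation set; baseline hazards are then
#' re-estimated on all training rows.
#'
#' @param x,time,event,treatment Training data (encoded matrix + outcomes).
#' @param config A [bsl_config()].
#' @param folds Optional fold assignment from [make_cv_folds()] (named by
#'   row position or plain integer vector along rows of `x`).
#' @param tune_grid Optional named list of candidate values for config
#'   fields, e.g. `list(lasso_lambda = c(0, 0.01), balance_alpha = c(0, 1))`.
#' @param val_fraction Fraction of training rows held out for early stopping
#'   in the final fit.
#' @param verbose Print tuning progress.
#' @return A fitted `bsl_model`; when tuning was performed, the selected
#'   configuration is recorded in `$config` and the CV table in `$cv_results`.
#' @export
train_bsl <- function(x, time, event, treatment, config = bsl_config(),
                      folds = NULL, tune_grid = NULL, val_fraction = 0.2,
                      verbose = FALSE) {
  x <- as.matrix(x)
  n <- nrow(x)
  cv_results <- NULL
  if (!is.null(tune_grid) && length(tune_grid)) {
    if (is.null(folds)) {
      folds <- make_cv_folds(seq_len(n), k = 5L, seed = config$seed)
    }
    grid <- expand.grid(tune_grid, KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
    scores <- numeric(nrow(grid))
    for (gi in seq_len(nrow(grid))) {
      cfg <- config
      for (nm in names(grid)) cfg[[nm]] <- grid[[nm]][gi]
      fold_losses <- vapply(sort(unique(folds)), function(k) {
        va <- which(folds == k); tr <- which(folds != k)
        fit <- bsl_fit(x[tr, , drop = FALSE], time[tr], event[tr],
                       treatment[tr], cfg,
                       validation = list(x = x[va, , drop = FALSE],
                                         time = time[va], event = event[va],
                                         treatment = treatment[va]))
        min(fit$history$validation_loss, na.rm = TRUE)
      }, numeric(1))
      scores[gi] <- mean(fold_losses)
      if (verbose) {
        message(sprintf("grid %d/%d: mean CV loss %.4f", gi, nrow(grid),
                        scores[gi]))
      }
    }
    best <- which.min(scores)
    for (nm in names(grid)) config[[nm]] <- grid[[nm]][best]
    cv_results <- cbind(grid, cv_loss = scores)
  }
  # internal early-stopping split, stratified on (arm, event)
  va <- with_seed(config$seed + 1L, {
    strata <- interaction(treatment, event, drop = TRUE)
    unlist(lapply(split(seq_len(n), strata), function(ii) {
      m <- max(1L, floor(val_fraction * length(ii)))
      if (length(ii) <= 1) return(integer(0))
      sample(ii, min(m, length(ii) - 1L))
    }), use.names = FALSE)
  })
  tr <- setdiff(seq_len(n), va)
  model <- bsl_fit(x[tr, , drop = FALSE], time[tr], event[tr], treatment[tr],
                   config,
                   validation = list(x = x[va, , drop = FALSE],
                                     time = time[va], event = event[va],
                                     treatment = treatment[va]),
                   verbose = verbose)
  model$cv_results <- cv_results
  model$horizon <- as.numeric(stats::quantile(time, 0.99))
  estimate_baselines(model, x, time, event, treatment)
}

#' @export
print.bsl_model <- function(x, ...) {
  cfg <- x$config
  cat("Balanced Survival Lasso-Network\n")
  cat(sprintf("  features: %d  shared: %s -> latent %d  head hidden: %s\n",
              x$n_features,
              paste(cfg$shared_layers, collapse = "-"),
              cfg$latent_dim,
              paste(cfg$head_hidden_layers, collapse = "-")))
  cat(sprintf("  lambda = %.4g, M = %.4g, alpha = %.4g, epsilon = %.4g\n",
              cfg$lasso_lambda, cfg$hierarchy_M, cfg$balance_alpha,
              cfg$ot_epsilon))
  cat(sprintf("  trained %d iterations (best at %d)\n",
              nrow(x$history), x$best_iter))
  for (arm in 0:1) {
    th <- x$params[[paste0("h", arm, "_theta")]]
    cat(sprintf("  head %d: %d/%d active skip weights\n", arm,
                sum(th != 0), length(th)))
  }
  invisible(x)
}

# features whose skip weight (and hence first-layer row) is exactly zero
dropped_features <- function(model, arm) {
  th <- model$params[[paste0("h", arm, "_theta")]]
  which(th == 0)
}
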