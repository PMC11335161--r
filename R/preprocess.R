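#' Columns of a cohort treated as model covariates
#'
#' Everything except the bookkeeping and outcome columns.
#' @param cohort Cohort `data.frame`.
#' @return Character vector of covariate column names.
#' @export
covariate_columns <- function(cohort) {
  setdiff(names(cohort),
          c("id", "treatment", "time", "event", "propensity",
            "true_log_hr", "true_ite_months"))
}

#' Encode cohort covariates as a numeric design matrix
#'
#' Continuous covariates are z-scored with mean and standard deviation
#' computed on the fitting subset only; two-level covariates become a single
#' 0/1 column; categoricals with three or more levels become a full one-hot
#' block (no reference level is dropped -- the downstream network is
#' penalized, so collinearity is harmless). The returned object keeps the
#' training statistics and level maps so test data is always transformed with
#' training-set parameters.
#'
#' @param cohort Cohort `data.frame` (no missing values).
#' @param fit_on Ids (values of `cohort$id`) on which encoding statistics are
#'   computed; defaults to all rows.
#' @param columns Covariate columns to encode; defaults to
#'   [covariate_columns()].
#' @return An object of class `bsl_encoded`: list with `x` (numeric matrix for
#'   all cohort rows), `ids`, and `encoder` (reusable via [apply_encoder()]).
#' @export
encode_features <- function(cohort, fit_on = cohort$id,
                            columns = covariate_columns(cohort)) {
  assert_cols(cohort, c("id", columns))
  if (anyNA(cohort[columns])) stop_bsl("cohort contains missing values")
  fit_rows <- cohort$id %in% fit_on
  if (!any(fit_rows)) stop_bsl("fit_on matches no cohort ids")

  enc <- list(columns = columns, spec = list())
  for (nm in columns) {
    v <- cohort[[nm]]
    if (is.numeric(v)) {
      m <- mean(v[fit_rows])
      s <- stats::sd(v[fit_rows])
      if (!is.finite(s) || s == 0) {
        stop_bsl("continuous covariate '%s' has zero variance on the fitting set", nm)
      }
      enc$spec[[nm]] <- list(kind = "continuous", mean = m, sd = s)
    } else {
      v <- as.factor(v)
      lev <- levels(droplevels(v[fit_rows]))
      if (length(lev) < 2) {
        stop_bsl("covariate '%s' has a single level on the fitting set", nm)
      }
      enc$spec[[nm]] <- list(
        kind = if (length(lev) == 2) "binary" else "categorical",
        levels = lev)
    }
  }
  class(enc) <- "bsl_encoder"
  x <- apply_encoder(enc, cohort)
  structure(list(x = x, ids = cohort$id, encoder = enc),
            class = "bsl_encoded")
}

#' Transform a cohort with a fitted encoder
#'
#' @param encoder A `bsl_encoder` from [encode_features()].
#' @param cohort Cohort `data.frame`; every categorical level must have been
#'   seen at fitting time.
#' @return Numeric design matrix with one row per cohort row.
#' @export
apply_encoder <- function(encoder, cohort) {
  stopifnot(inherits(encoder, "bsl_encoder"))
  cols <- list()
  for (nm in encoder$columns) {
    sp <- encoder$spec[[nm]]
    v <- cohort[[nm]]
    if (is.null(v)) stop_bsl("cohort is missing covariate '%s'", nm)
    if (sp$kind == "continuous") {
      cols[[nm]] <- matrix((as.numeric(v) - sp$mean) / sp$sd,
                           dimnames = list(NULL, nm))
    } else {
      v <- as.character(v)
      unseen <- setdiff(unique(v), sp$levels)
      if (length(unseen)) {
        stop_bsl("covariate '%s' has level(s) unseen at fitting time: %s",
                 nm, paste(unseen, collapse = ", "))
      }
      if (sp$kind == "binary") {
        cols[[nm]] <- matrix(as.numeric(v == sp$levels[2]),
                             dimnames = list(NULL, paste0(nm, "_", sp$levels[2])))
      } else {
        block <- vapply(sp$levels, function(l) as.numeric(v == l),
                        numeric(length(v)))
        colnames(block) <- paste0(nm, "_", sp$levels)
        cols[[nm]] <- block
      }
    }
  }
  do.call(cbind, cols)
}

#' Recover original covariate labels from an encoded matrix
#'
#' Inverse of [apply_encoder()]: z-scores are mapped back to raw units and
#' one-hot blocks back to their level labels.
#'
#' @param encoder A `bsl_encoder`.
#' @param x Encoded matrix produced with the same encoder.
#' @return A `data.frame` of decoded covariates.
#' @export
decode_features <- function(encoder, x) {
  stopifnot(inherits(encoder, "bsl_encoder"))
  out <- list()
  for (nm in encoder$columns) {
    sp <- encoder$spec[[nm]]
    if (sp$kind == "continuous") {
      out[[nm]] <- x[, nm] * sp$sd + sp$mean
    } else if (sp$kind == "binary") {
      out[[nm]] <- sp$levels[1 + (x[, paste0(nm, "_", sp$levels[2])] > 0.5)]
    } else {
      block <- x[, paste0(nm, "_", sp$levels), drop = FALSE]
      out[[nm]] <- sp$levels[max.col(block)]
    }
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Split a cohort into training and test sets
#'
#' The test set holds `floor(test_fraction * n)` patients. By default the
#' split is stratified on (treatment, event) with largest-remainder
#' allocation, which stabilizes small cohorts; set `stratify = FALSE` for a
#' plain random split.
#'
#' @param cohort Cohort `data.frame` with an `id` column.
#' @param test_fraction Fraction held out, in (0, 1). Default 0.2.
#' @param seed Integer seed; the split is deterministic given it.
#' @param stratify Stratify on (treatment, event)? Default `TRUE`.
#' @return An object of class `bsl_split`: list with `train_ids`, `test_ids`,
#'   `test_fraction`, `seed`.
#' @export
split_cohort <- function(cohort, test_fraction = 0.2, seed = 1L,
                         stratify = TRUE) {
  assert_cols(cohort, "id")
  n <- nrow(cohort)
  if (n < 10) stop_bsl("cohort too small to split (n = %d < 10)", n)
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop_bsl("test_fraction must lie in (0, 1)")
  }
  m <- floor(test_fraction * n)
  with_seed(seed, {
    if (stratify && all(c("treatment", "event") %in% names(cohort))) {
      strata <- interaction(cohort$treatment, cohort$event, drop = TRUE)
      # largest-remainder apportionment of the m test slots across strata
      sizes <- table(strata)
      exact <- as.numeric(sizes) * m / n
      base <- floor(exact)
      rem <- m - sum(base)
      if (rem > 0) {
        order_rem <- order(exact - base, decreasing = TRUE)
        base[order_rem[seq_len(rem)]] <- base[order_rem[seq_len(rem)]] + 1
      }
      test_ids <- integer(0)
      for (k in seq_along(sizes)) {
        ids_k <- cohort$id[strata == names(sizes)[k]]
        take <- min(base[k], length(ids_k))
        test_ids <- c(test_ids, sample(ids_k, take))
      }
      # top up from the remainder if a stratum was too small
      if (length(test_ids) < m) {
        pool <- setdiff(cohort$id, test_ids)
        test_ids <- c(test_ids, sample(pool, m - length(test_ids)))
      }
    } else {
      test_ids <- sample(cohort$id, m)
    }
    structure(list(
      train_ids = sort(setdiff(cohort$id, test_ids)),
      test_ids = sort(test_ids),
      test_fraction = test_fraction,
      seed = as.integer(seed)
    ), class = "bsl_split")
  })
}

#' Assign 5-fold (or k-fold) cross-validation folds to the training ids
#'
#' Folds partition the training ids into near-equal parts (sizes differ by at
#' most one): each tuning round trains on k-1 folds and validates on the
#' held-out fold.
#'
#' @param split A `bsl_split` from [split_cohort()], or a vector of ids.
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @return Named integer vector: fold index (1..k) per training id.
#' @export
make_cv_folds <- function(split, k = 5L, seed = 1L) {
  ids <- if (inherits(split, "bsl_split")) split$train_ids else split
  n <- length(ids)
  if (k > n) stop_bsl("cannot make %d folds from %d training ids", k, n)
  with_seed(seed, {
    fold <- sample(rep(seq_len(k), length.out = n))
    stats::setNames(as.integer(fold), ids)
  })
}

#' Write / read a split plan as a two-column CSV
#' @param split A `bsl_split`.
#' @param path File path.
#' @return `path` (write) or a `bsl_split` (read).
#' @export
write_split <- function(split, path) {
  stopifnot(inherits(split, "bsl_split"))
  df <- data.frame(
    id = c(split$train_ids, split$test_ids),
    assignment = c(rep("train", length(split$train_ids)),
                   rep("test", length(split$test_ids))))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_split
#' @export
read_split <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  structure(list(
    train_ids = sort(df$id[df$assignment == "train"]),
    test_ids = sort(df$id[df$assignment == "test"]),
    test_fraction = NA_real_, seed = NA_integer_
  ), class = "bsl_split")
}
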