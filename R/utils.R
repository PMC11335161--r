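# Internal helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so library code never clobbers user RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# numerically stable log(sum(exp(v)))
logsumexp <- function(v) {
  m <- max(v)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(v - m)))
}

# row-wise logsumexp of a matrix (max.col keeps this C-speed)
row_logsumexp <- function(m) {
  mx <- m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]
  mx + log(rowSums(exp(m - mx)))
}

stop_bsl <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warn_bsl <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

assert_cols <- function(df, cols, what = "cohort") {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop_bsl("%s is missing required column(s): %s", what,
             paste(miss, collapse = ", "))
  }
}

is_binary01 <- function(x) all(x %in% c(0, 1))
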