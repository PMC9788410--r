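# Internal helpers shared across the package.

#' Evaluate an expression under a fixed RNG seed
#'
#' Saves and restores the caller's RNG state so seeded package functions do
#' not disturb the global random stream.
#'
#' @param seed integer seed, or NULL to leave the RNG alone.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

# Deterministically derive a stream of child seeds from a master seed.
# Order of consumption is fixed and documented where used: callers index by
# position, so adding streams later never reshuffles earlier ones.
derive_seeds <- function(master_seed, n) {
  with_seed(master_seed, sample.int(.Machine$integer.max - 1L, n))
}

# Sample standard deviation that tolerates length-1 input (returns NA).
sd_sample <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# stratified fold assignment; classification stratifies by label,
# regression by response quantile blocks.  Returns integer fold ids 1..k.
stratified_folds <- function(y, k, task = c("classification", "regression")) {
  task <- match.arg(task)
  n <- length(y)
  folds <- integer(n)
  if (task == "classification") {
    for (lev in unique(y)) {
      idx <- which(y == lev)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(sample.int(k), length(idx))
    }
  } else {
    ord <- order(y + stats::runif(n) * 1e-9)  # jitter breaks ties randomly
    # walk consecutive response blocks, spreading each across folds
    for (start in seq(1L, n, by = k)) {
      block <- ord[start:min(start + k - 1L, n)]
      folds[block] <- sample.int(k)[seq_along(block)]
    }
  }
  folds
}
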