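# Random-forest regression ranking by permutation importance (mean decrease
# in accuracy, i.e. OOB error increase under per-feature permutation).

#' Rank features by random-forest permutation importance
#'
#' Fits a bagged regression forest and ranks features by the unscaled mean
#' decrease in accuracy: the average increase in out-of-bag MSE when the
#' feature is permuted, in response-squared units.
#'
#' @param X numeric n x p predictor matrix.
#' @param y numeric response vector.
#' @param n_trees number of trees (default 500).
#' @param mtry predictors sampled per split (default ceiling(p/3), the
#'   regression convention).
#' @param seed integer seed; same seed gives identical ranks.
#' @return list with `forest` (the randomForest fit) and `ranks` (data.frame
#'   `feature`, `score` = MDA, `rank` with 1 = most important, ties broken
#'   by feature order).
#' @export
rf_rank <- function(X, y, n_trees = 500, mtry = NULL, seed = 1L) {
  X <- as.matrix(X)
  stopifnot(nrow(X) >= 5L, length(y) == nrow(X))
  if (n_trees < 1) stopf("n_trees must be >= 1")
  if (is.null(mtry)) mtry <- max(1L, ceiling(ncol(X) / 3))
  fit <- with_seed(seed,
    randomForest::randomForest(x = X, y = as.numeric(y), ntree = n_trees,
                               mtry = mtry, importance = TRUE))
  imp <- randomForest::importance(fit, type = 1, scale = FALSE)[, 1L]
  feats <- colnames(X)
  if (is.null(feats)) feats <- sprintf("X%d", seq_len(ncol(X)))
  list(forest = fit,
       ranks = data.frame(feature = feats, score = as.numeric(imp),
                          rank = rank(-imp, ties.method = "first"),
                          stringsAsFactors = FALSE))
}
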