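# Model-performance metrics: balanced accuracy from per-class rates,
# cross-validated Q-squared, RMSEP.

#' Per-class confusion summary
#'
#' @param truth true labels.
#' @param pred predicted labels (same length).
#' @return a `confusion_summary`: data.frame with per-class `TPR`, `TNR`
#'   and counts.
#' @export
confusion_summary <- function(truth, pred) {
  truth <- as.character(truth); pred <- as.character(pred)
  stopifnot(length(truth) == length(pred))
  classes <- sort(unique(truth))
  rows <- lapply(classes, function(cl) {
    is_cl <- truth == cl
    if (!any(is_cl) || all(is_cl)) {
      stopf("class '%s' is empty or exhaustive; rates undefined", cl)
    }
    data.frame(class = cl,
               n = sum(is_cl),
               TPR = mean(pred[is_cl] == cl),
               TNR = mean(pred[!is_cl] != cl),
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), class = c("confusion_summary", "data.frame"))
}

#' Balanced accuracy
#'
#' `BACC = sum_i (TPR_i + TNR_i) / (2L)` over the L classes; 0.5 is the
#' random baseline for a binary problem.
#'
#' @param x a [confusion_summary()], or true labels (then `pred` required).
#' @param pred predicted labels when `x` is the truth vector.
#' @return balanced accuracy in [0, 1].
#' @export
balanced_accuracy <- function(x, pred = NULL) {
  cs <- if (inherits(x, "confusion_summary")) x else confusion_summary(x, pred)
  if (nrow(cs) < 2L) stopf("balanced accuracy needs >= 2 classes")
  sum(cs$TPR + cs$TNR) / (2 * nrow(cs))
}

#' Cross-validated Q-squared
#'
#' `Q2 = 1 - PRESS/TSS = 1 - sum((y - yhat_cv)^2) / sum((y - mean(y))^2)`,
#' where `yhat_cv` are out-of-fold predictions (sample j predicted by a
#' model that never saw sample j).
#'
#' @param y observed responses.
#' @param yhat_cv out-of-fold predictions, same length.
#' @return Q2 (at most 1; negative when predictions are worse than the mean).
#' @export
q_squared <- function(y, yhat_cv) {
  stopifnot(length(y) == length(yhat_cv), length(y) >= 2L)
  tss <- sum((y - mean(y))^2)
  if (tss == 0) stopf("constant response: Q2 undefined")
  1 - sum((y - yhat_cv)^2) / tss
}

#' Root-mean-squared error of prediction
#'
#' @param y observed responses.
#' @param yhat_cv out-of-fold predictions.
#' @return RMSEP in response units.
#' @export
rmsep <- function(y, yhat_cv) {
  stopifnot(length(y) == length(yhat_cv))
  sqrt(mean((y - yhat_cv)^2))
}
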