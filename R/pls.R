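# Partial least squares by NIPALS with standard deflation, VIP importance
# and one-hot PLS-DA decoding.  Written as the package's own estimator: the
# rdCV engine refits it thousands of times, so the implementation is kept
# lean (crossprod-based, special-cased for single-response Y).

#' Fit a partial least squares model (NIPALS)
#'
#' X and Y are mean-centered internally (no scaling: autoscale upstream when
#' wanted). For a single-response Y each component has the closed-form
#' weight `w = X'y / ||X'y||`; multi-response Y uses the iterative NIPALS
#' inner loop. X is deflated by `t p'` after each component, Y by `t q'`.
#'
#' @param X numeric n x p predictor matrix.
#' @param Y numeric response: vector, or n x m matrix (e.g. one-hot classes
#'   for PLS-DA).
#' @param ncomp number of latent components A (reduced with a warning if it
#'   exceeds the data rank).
#' @param tol convergence tolerance of the NIPALS inner loop.
#' @return an object of class `pls_model` with weights `W`, X-loadings `P`,
#'   Y-loadings `Q`, scores `T`, per-component regression coefficients
#'   (cumulative) `B` (p x m x A), centers, and per-component explained
#'   Y-variance `ssy`.
#' @export
pls_fit <- function(X, Y, ncomp = 2, tol = 1e-10) {
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  n <- nrow(X); p <- ncol(X); m <- ncol(Y)
  stopifnot(n >= 2, nrow(Y) == n)
  x_center <- colMeans(X)
  y_center <- colMeans(Y)
  Xc <- sweep(X, 2L, x_center)
  Yc <- sweep(Y, 2L, y_center)
  max_a <- min(n - 1L, p)
  if (ncomp > max_a) {
    warnf("ncomp reduced from %d to %d (rank limit)", ncomp, max_a)
    ncomp <- max_a
  }
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  Q <- matrix(0, m, ncomp); Tm <- matrix(0, n, ncomp)
  ssy <- numeric(ncomp)
  Xa <- Xc; Ya <- Yc
  a <- 0L
  while (a < ncomp) {
    if (m == 1L) {
      w <- crossprod(Xa, Ya)[, 1L]
      nw <- sqrt(sum(w^2))
      if (nw < 1e-14) break
      w <- w / nw
      tt <- Xa %*% w
      tt2 <- sum(tt^2)
      if (tt2 < 1e-14) break
      q <- crossprod(Ya, tt)[, 1L] / tt2
    } else {
      u <- Ya[, which.max(apply(Ya, 2L, stats::var))]
      w <- numeric(p)
      for (it in seq_len(200L)) {
        w_new <- crossprod(Xa, u)[, 1L]
        nw <- sqrt(sum(w_new^2))
        if (nw < 1e-14) break
        w_new <- w_new / nw
        tt <- Xa %*% w_new
        tt2 <- sum(tt^2)
        if (tt2 < 1e-14) break
        q <- crossprod(Ya, tt)[, 1L] / tt2
        u_new <- (Ya %*% q) / sum(q^2)
        delta <- sum((w_new - w)^2)
        w <- w_new
        u <- u_new[, 1L]
        if (delta < tol) break
      }
      nw <- sqrt(sum(w^2))
      if (nw < 1e-14) break
      tt <- Xa %*% w
      tt2 <- sum(tt^2)
      if (tt2 < 1e-14) break
      q <- crossprod(Ya, tt)[, 1L] / tt2
    }
    a <- a + 1L
    pl <- crossprod(Xa, tt)[, 1L] / tt2
    W[, a] <- w; P[, a] <- pl; Q[, a] <- q; Tm[, a] <- tt
    ssy[a] <- tt2 * sum(q^2)  # Y-variance captured by this component
    Xa <- Xa - tt %*% t(pl)
    Ya <- Ya - tt %*% t(q)
  }
  if (a == 0L) stopf("PLS found no informative component (X'Y is zero)")
  if (a < ncomp) {
    W <- W[, seq_len(a), drop = FALSE]; P <- P[, seq_len(a), drop = FALSE]
    Q <- Q[, seq_len(a), drop = FALSE]; Tm <- Tm[, seq_len(a), drop = FALSE]
    ssy <- ssy[seq_len(a)]
  }
  # cumulative coefficients for 1..a components: B_a = W (P'W)^-1 Q'
  B <- array(0, dim = c(p, m, a))
  PW <- crossprod(P, W)
  for (k in seq_len(a)) {
    Rk <- W[, seq_len(k), drop = FALSE] %*%
      solve(PW[seq_len(k), seq_len(k), drop = FALSE])
    B[, , k] <- Rk %*% t(Q[, seq_len(k), drop = FALSE])
  }
  structure(list(ncomp = a, W = W, P = P, Q = Q, T = Tm, B = B,
                 x_center = x_center, y_center = y_center, ssy = ssy,
                 Y = Y,
                 feature_names = colnames(X),
                 response_names = colnames(Y)),
            class = "pls_model")
}

#' Predict from a PLS model
#'
#' @param object a `pls_model`.
#' @param newdata matrix of new samples (columns must match training
#'   features).
#' @param ncomp number of components to use (default: all fitted).
#' @param ... unused.
#' @return predicted response matrix (n x m).
#' @export
predict.pls_model <- function(object, newdata, ncomp = object$ncomp, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$x_center)) {
    stopf("newdata has %d features; model was trained on %d",
          ncol(newdata), length(object$x_center))
  }
  ncomp <- min(ncomp, object$ncomp)
  Xc <- sweep(newdata, 2L, object$x_center)
  pred <- Xc %*% object$B[, , ncomp]
  sweep(pred, 2L, object$y_center, "+")
}

#' @export
coef.pls_model <- function(object, ncomp = object$ncomp, ...) {
  object$B[, , min(ncomp, object$ncomp)]
}

#' @export
fitted.pls_model <- function(object, ...) {
  sweep(object$T %*% t(object$Q), 2L, object$y_center, "+")
}

#' @export
residuals.pls_model <- function(object, ...) {
  object$Y - fitted(object)
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("PLS model: %d feature(s), %d response column(s), %d component(s)\n",
              nrow(x$W), nrow(x$Q), x$ncomp))
  ev <- x$ssy / sum(x$ssy)
  cat("  Y-variance share per component:",
      paste(sprintf("%.3f", ev), collapse = " "), "\n")
  invisible(x)
}

#' Variable importance in projection
#'
#' `VIP_f = sqrt(p * sum_a SS_a (w_af / ||w_a||)^2 / sum_a SS_a)` with
#' `SS_a` the Y-variance captured by component a; squared VIPs average to 1
#' over features.
#'
#' @param model a fitted `pls_model`.
#' @return data.frame with `feature`, `score` (VIP) and `rank` (1 = most
#'   important; ties broken by feature order).
#' @export
vip <- function(model) {
  stopifnot(inherits(model, "pls_model"))
  if (sum(model$ssy) <= 0) stopf("model explains no Y variance; VIP undefined")
  W2 <- sweep(model$W^2, 2L, colSums(model$W^2), "/")
  p <- nrow(model$W)
  v <- sqrt(p * as.vector(W2 %*% model$ssy) / sum(model$ssy))
  feats <- model$feature_names
  if (is.null(feats)) feats <- sprintf("X%d", seq_len(p))
  data.frame(feature = feats, score = v,
             rank = rank(-v, ties.method = "first"),
             stringsAsFactors = FALSE)
}

# one-hot encode class labels, column order = order of first appearance in
# training (the documented tie-break order for decoding)
one_hot <- function(labels) {
  labels <- as.character(labels)
  levs <- unique(labels)
  Y <- matrix(0, length(labels), length(levs),
              dimnames = list(NULL, levs))
  Y[cbind(seq_along(labels), match(labels, levs))] <- 1
  Y
}

#' PLS-DA class prediction
#'
#' Decodes one-hot dummy predictions by argmax; exact ties go to the label
#' that appeared first in training order.
#'
#' @param model a `pls_model` trained on one-hot dummy Y.
#' @param newdata matrix of new samples.
#' @param ncomp components to use.
#' @return character vector of predicted labels.
#' @export
plsda_predict <- function(model, newdata, ncomp = model$ncomp) {
  pred <- predict(model, newdata, ncomp = ncomp)
  labs <- model$response_names
  if (is.null(labs)) labs <- sprintf("class%d", ncol(pred))
  labs[apply(pred, 1L, which.max)]  # which.max takes the first on ties
}
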