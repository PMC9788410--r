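# Repeated double cross-validation (rdCV) feature elimination.
#
# Per repetition: samples are split into n_outer stratified folds; with each
# outer fold held out, an inner n_inner-fold CV walks a descending feature
# ladder (drop the least-important elimination_fraction per step, geometric,
# floor 2), recording the inner validation error and per-feature importance
# (VIP for PLS, permutation MDA for RF) at every rung.  The validation curve
# defines the minimal-optimal ("min"), all-relevant ("max") and geometric-
# mean ("mid") predictor counts; models refitted on the outer-training set
# at those sizes predict the held-out fold.  Ranks and fold sizes are fused
# across outer folds and repetitions by arithmetic means/medians, and the
# final performance (BACC or Q2) is computed from the pooled out-of-fold
# predictions only.

#' rdCV selection configuration
#'
#' @param task "classification" or "regression".
#' @param engine "pls" (VIP ranking) or "rf" (permutation-importance
#'   ranking; regression only).
#' @param n_outer outer folds (default 4 for classification, 9 for
#'   regression).
#' @param n_repetitions repetitions with reshuffled folds (default 500
#'   classification / 200 regression; scale down for desk runs).
#' @param n_inner inner folds (default `n_outer - 1`).
#' @param elimination_fraction fraction of retained features dropped per
#'   ladder step (default 0.10).
#' @param max_components PLS component ceiling; the inner CV picks the
#'   argmin over 1..max_components at each rung (default 5).
#' @param tolerance fraction above the minimal inner error that still counts
#'   as optimal when locating the min/max set sizes (default 0.05).
#' @param n_trees trees per RF fit inside the engine (default 100).
#' @param seed master seed; per-repetition child seeds are derived from it.
#' @return a `selection_config` list.
#' @export
selection_config <- function(task = c("classification", "regression"),
                             engine = c("pls", "rf"),
                             n_outer = NULL, n_repetitions = NULL,
                             n_inner = NULL,
                             elimination_fraction = 0.10,
                             max_components = 5, tolerance = 0.05,
                             n_trees = 100, seed = 1L) {
  task <- match.arg(task)
  engine <- match.arg(engine)
  if (task == "classification" && engine == "rf") {
    stopf("the rf engine is regression-only")
  }
  if (is.null(n_outer)) n_outer <- if (task == "classification") 4L else 9L
  if (is.null(n_repetitions)) {
    n_repetitions <- if (task == "classification") 500L else 200L
  }
  if (is.null(n_inner)) n_inner <- max(2L, n_outer - 1L)
  stopifnot(n_outer >= 2, n_inner >= 2,
            elimination_fraction > 0, elimination_fraction < 1,
            tolerance >= 0, max_components >= 1)
  structure(list(task = task, engine = engine, n_outer = as.integer(n_outer),
                 n_repetitions = as.integer(n_repetitions),
                 n_inner = as.integer(n_inner),
                 elimination_fraction = elimination_fraction,
                 max_components = as.integer(max_components),
                 tolerance = tolerance, n_trees = as.integer(n_trees),
                 seed = as.integer(seed)),
            class = "selection_config")
}

# descending ladder of feature counts: drop elimination_fraction
# (at least one feature) per step, floor 2
feature_ladder <- function(p, elim) {
  sizes <- p
  while (sizes[length(sizes)] > 2L) {
    s <- sizes[length(sizes)]
    sizes <- c(sizes, max(2L, s - max(1L, round(elim * s))))
  }
  sizes
}

# inner engine fit/evaluate at one ladder rung.
# returns list(err = scalar inner error, best_a, importance = named vector)
inner_step <- function(X, y, Y1h, feats, inner_folds, cfg) {
  n_inner <- max(inner_folds)
  p_cur <- length(feats)
  if (cfg$engine == "pls") {
    a_max <- 1L
    fold_fits <- vector("list", n_inner)
    for (f in seq_len(n_inner)) {
      tr <- inner_folds != f
      if (sum(tr) < 2L) next
      Xtr <- X[tr, feats, drop = FALSE]
      Ytr <- if (cfg$task == "classification") {
        Y1h[tr, , drop = FALSE]
      } else {
        matrix(y[tr], ncol = 1L)
      }
      A <- min(cfg$max_components, sum(tr) - 1L, p_cur)
      fit <- tryCatch(pls_fit(Xtr, Ytr, ncomp = A),
                      error = function(e) NULL)
      if (is.null(fit)) next
      a_max <- max(a_max, fit$ncomp)
      fold_fits[[f]] <- fit
    }
    err_a <- matrix(NA_real_, n_inner, a_max)
    for (f in seq_len(n_inner)) {
      fit <- fold_fits[[f]]
      if (is.null(fit)) next
      va <- inner_folds == f
      Xv <- X[va, feats, drop = FALSE]
      for (a in seq_len(fit$ncomp)) {
        pr <- predict(fit, Xv, ncomp = a)
        err_a[f, a] <- if (cfg$task == "classification") {
          labs <- colnames(Y1h)[apply(pr, 1L, which.max)]
          sum(labs != y[va])
        } else {
          sum((pr[, 1L] - y[va])^2)
        }
      }
      if (fit$ncomp < a_max) {  # carry last available component forward
        err_a[f, (fit$ncomp + 1L):a_max] <- err_a[f, fit$ncomp]
      }
    }
    tot <- colSums(err_a, na.rm = TRUE)
    best_a <- which.min(tot)
    imp <- numeric(p_cur)
    n_ok <- 0L
    for (f in seq_len(n_inner)) {
      fit <- fold_fits[[f]]
      if (is.null(fit)) next
      a_use <- min(best_a, fit$ncomp)
      W2 <- sweep(fit$W^2, 2L, colSums(fit$W^2), "/")
      ssy <- fit$ssy[seq_len(a_use)]
      if (sum(ssy) <= 0) next
      imp <- imp + sqrt(p_cur *
                          as.vector(W2[, seq_len(a_use), drop = FALSE] %*% ssy) /
                          sum(ssy))
      n_ok <- n_ok + 1L
    }
    if (n_ok == 0L) imp <- stats::runif(p_cur)  # degenerate rung: random order
    list(err = sum(tot[best_a]), best_a = best_a,
         importance = stats::setNames(imp, feats))
  } else {
    err <- 0
    imp <- numeric(p_cur)
    for (f in seq_len(n_inner)) {
      tr <- inner_folds != f
      fit <- randomForest::randomForest(
        x = X[tr, feats, drop = FALSE], y = y[tr], ntree = cfg$n_trees,
        mtry = max(1L, ceiling(p_cur / 3)), importance = TRUE)
      pr <- stats::predict(fit, X[inner_folds == f, feats, drop = FALSE])
      err <- err + sum((pr - y[inner_folds == f])^2)
      imp <- imp + randomForest::importance(fit, type = 1, scale = FALSE)[, 1L]
    }
    list(err = err, best_a = NA_integer_,
         importance = stats::setNames(imp, feats))
  }
}

# refit the engine on the whole outer-training set at a chosen feature set
# and predict the held-out fold
outer_predict <- function(X, y, Y1h, feats, tr, te, best_a, cfg) {
  if (cfg$engine == "pls") {
    Ytr <- if (cfg$task == "classification") {
      Y1h[tr, , drop = FALSE]
    } else {
      matrix(y[tr], ncol = 1L)
    }
    A <- min(if (is.na(best_a)) cfg$max_components else best_a,
             sum(tr) - 1L, length(feats))
    fit <- pls_fit(X[tr, feats, drop = FALSE], Ytr, ncomp = A)
    pr <- predict(fit, X[te, feats, drop = FALSE])
    if (cfg$task == "classification") {
      colnames(Y1h)[apply(pr, 1L, which.max)]
    } else {
      pr[, 1L]
    }
  } else {
    fit <- randomForest::randomForest(
      x = X[tr, feats, drop = FALSE], y = y[tr], ntree = cfg$n_trees,
      mtry = max(1L, ceiling(length(feats) / 3)))
    as.numeric(stats::predict(fit, X[te, feats, drop = FALSE]))
  }
}

#' Repeated double cross-validated feature selection
#'
#' The package's core estimator: ranks features by repeated
#' double cross-validated elimination and estimates generalization
#' performance from pooled out-of-fold predictions. See the package
#' vignette for the algorithm.
#'
#' @param X numeric samples x features matrix (preprocessed/autoscaled).
#' @param y class labels (classification) or numeric response (regression).
#' @param cfg a [selection_config()].
#' @return an object of class `rdcv_result`: average `ranks`, set sizes
#'   `n_min`/`n_mid`/`n_max`, nested feature sets `set_min` ⊆ `set_mid` ⊆
#'   `set_max`, the inner `validation_curve`, pooled out-of-fold
#'   `performance` (BACC or Q2) at each set size, and the config echo.
#' @export
rdcv_select <- function(X, y, cfg = selection_config()) {
  X <- as.matrix(X)
  stopifnot(inherits(cfg, "selection_config"))
  n <- nrow(X); p <- ncol(X)
  if (is.null(colnames(X))) colnames(X) <- sprintf("X%d", seq_len(p))
  feats_all <- colnames(X)
  if (all(apply(X, 2L, function(v) sd_sample(v) == 0 || is.na(sd_sample(v))))) {
    stopf("all features are constant")
  }
  if (cfg$task == "classification") {
    y <- as.character(y)
    tab <- table(y)
    if (any(tab < cfg$n_outer)) {
      stopf("class '%s' has %d member(s), fewer than n_outer = %d",
            names(tab)[which.min(tab)], min(tab), cfg$n_outer)
    }
    Y1h <- one_hot(y)
  } else {
    y <- as.numeric(y)
    if (sd_sample(y) == 0) stopf("constant response")
    Y1h <- NULL
  }
  ladder <- feature_ladder(p, cfg$elimination_fraction)
  rep_seeds <- derive_seeds(cfg$seed, cfg$n_repetitions)

  rank_sum <- stats::setNames(numeric(p), feats_all)
  rank_n <- 0L
  curve_err <- stats::setNames(numeric(length(ladder)),
                               as.character(ladder))
  curve_n <- curve_err
  sizes_rec <- list(min = integer(0), mid = integer(0), max = integer(0))
  pooled <- list(min = list(y = c(), yhat = c()),
                 mid = list(y = c(), yhat = c()),
                 max = list(y = c(), yhat = c()))

  for (r in seq_len(cfg$n_repetitions)) {
    with_seed(rep_seeds[r], {
      outer_folds <- stratified_folds(y, cfg$n_outer, cfg$task)
      for (o in seq_len(cfg$n_outer)) {
        tr <- which(outer_folds != o)
        te <- which(outer_folds == o)
        if (length(te) == 0L || length(tr) < cfg$n_inner) next
        inner_folds_all <- stratified_folds(y[tr], cfg$n_inner, cfg$task)
        Y1h_tr <- if (is.null(Y1h)) NULL else Y1h[tr, , drop = FALSE]
        feats <- feats_all
        step_rank_sum <- stats::setNames(numeric(p), feats_all)
        n_steps <- 0L
        errs <- numeric(length(ladder))
        best_as <- integer(length(ladder))
        sets <- vector("list", length(ladder))
        for (li in seq_along(ladder)) {
          s <- ladder[li]
          # current rung keeps the top-s features from the previous rung
          st <- inner_step(X[tr, , drop = FALSE], y[tr], Y1h_tr,
                           feats, inner_folds_all, cfg)
          errs[li] <- st$err
          best_as[li] <- st$best_a
          sets[[li]] <- feats
          # per-rung rank contribution: present features ranked by
          # importance, absent features get rung size + 1
          rk <- rep(s + 1, p)
          names(rk) <- feats_all
          rk[feats] <- rank(-st$importance, ties.method = "first")
          step_rank_sum <- step_rank_sum + rk
          n_steps <- n_steps + 1L
          curve_err[li] <- curve_err[li] + st$err
          curve_n[li] <- curve_n[li] + 1L
          if (li < length(ladder)) {
            keep <- ladder[li + 1L]
            ord <- order(-st$importance)
            feats <- feats[sort(ord[seq_len(keep)])]
          }
        }
        emin <- min(errs)
        ok <- which(errs <= (1 + cfg$tolerance) * emin)
        li_min <- max(ok)  # deepest rung (smallest size) still optimal
        li_max <- min(ok)  # shallowest rung (largest size)
        gm <- sqrt(as.numeric(ladder[li_min]) * ladder[li_max])
        li_mid <- which.min(abs(ladder - gm))
        picks <- c(min = li_min, mid = li_mid, max = li_max)
        for (nm in names(picks)) {
          li <- picks[[nm]]
          pred <- outer_predict(X, y, Y1h, sets[[li]], tr, te,
                                best_as[li], cfg)
          pooled[[nm]]$y <- c(pooled[[nm]]$y, y[te])
          pooled[[nm]]$yhat <- c(pooled[[nm]]$yhat, pred)
          sizes_rec[[nm]] <- c(sizes_rec[[nm]], ladder[li])
        }
        rank_sum <- rank_sum + step_rank_sum / n_steps
        rank_n <- rank_n + 1L
      }
    })
  }
  if (rank_n == 0L) stopf("no outer fold produced a model")

  avg_rank <- rank_sum / rank_n
  ord <- order(avg_rank, feats_all)
  n_min <- as.integer(round(stats::median(sizes_rec$min)))
  n_mid <- as.integer(round(stats::median(sizes_rec$mid)))
  n_max <- as.integer(round(stats::median(sizes_rec$max)))
  # enforce ordering (medians are taken per set independently)
  n_mid <- max(n_mid, n_min); n_max <- max(n_max, n_mid)
  set_min <- feats_all[ord][seq_len(n_min)]
  set_mid <- feats_all[ord][seq_len(n_mid)]
  set_max <- feats_all[ord][seq_len(n_max)]

  perf <- sapply(c("min", "mid", "max"), function(nm) {
    if (cfg$task == "classification") {
      balanced_accuracy(pooled[[nm]]$y, pooled[[nm]]$yhat)
    } else {
      q_squared(pooled[[nm]]$y, pooled[[nm]]$yhat)
    }
  })

  structure(list(
    ranks = data.frame(feature = feats_all[ord],
                       avg_rank = avg_rank[ord],
                       row.names = NULL, stringsAsFactors = FALSE),
    n_min = n_min, n_mid = n_mid, n_max = n_max,
    set_min = set_min, set_mid = set_mid, set_max = set_max,
    validation_curve = data.frame(
      n_features = ladder,
      inner_error = ifelse(curve_n > 0, curve_err / pmax(curve_n, 1L), NA),
      row.names = NULL),
    performance = unname(perf["mid"]),
    performance_by_set = perf,
    metric = if (cfg$task == "classification") "BACC" else "Q2",
    outer_predictions = pooled,
    config = cfg),
    class = "rdcv_result")
}

#' @export
print.rdcv_result <- function(x, ...) {
  cat(sprintf("rdCV %s (%s engine): %d repetitions x %d outer folds\n",
              x$config$task, x$config$engine, x$config$n_repetitions,
              x$config$n_outer))
  cat(sprintf("  set sizes: min %d <= mid %d <= max %d (of %d features)\n",
              x$n_min, x$n_mid, x$n_max, nrow(x$ranks)))
  cat(sprintf("  %s (pooled out-of-fold, min/mid/max): %.3f / %.3f / %.3f\n",
              x$metric, x$performance_by_set[["min"]],
              x$performance_by_set[["mid"]], x$performance_by_set[["max"]]))
  invisible(x)
}

#' @export
summary.rdcv_result <- function(object, n = 10L, ...) {
  print(object)
  cat("\nTop-ranked features:\n")
  print(utils::head(object$ranks, n))
  invisible(object)
}

#' @export
plot.rdcv_result <- function(x, ...) {
  vc <- x$validation_curve
  plot(vc$n_features, vc$inner_error, log = "x", type = "b", pch = 16,
       xlab = "retained features", ylab = "mean inner validation error",
       main = sprintf("rdCV validation curve (%s)", x$metric), ...)
  graphics::abline(v = c(x$n_min, x$n_mid, x$n_max), lty = 3)
  invisible(x)
}

#' Classify a compositional factor from each platform
#'
#' Runs one rdCV PLS-DA per platform table with the design factor's levels
#' as class labels — the platform x factor classification grid.
#'
#' @param tables named list of product-level matrices (or processed
#'   `feature_table`s / the sensory-response matrix); rows must be named by
#'   product id.
#' @param design a `study_design`.
#' @param factor_name one of `oil_type`, `tomato_dose`, `yeast_product`,
#'   `yeast_dose`, `heat`.
#' @param cfg a classification [selection_config()]; `n_outer` is capped at
#'   the smallest class count.
#' @return named list of `rdcv_result`s (NULL with a warning for a
#'   single-level factor).
#' @export
classify_composition <- function(tables, design, factor_name,
                                 cfg = selection_config("classification")) {
  stopifnot(inherits(design, "study_design"))
  if (!factor_name %in% setdiff(.design_cols, "product_id")) {
    stopf("unknown compositional factor '%s'", factor_name)
  }
  lv <- design[[factor_name]]
  if (length(unique(lv)) < 2L) {
    warnf("factor '%s' has a single level; skipped", factor_name)
    return(NULL)
  }
  lapply(tables, function(tab) {
    x <- if (inherits(tab, "feature_table")) tab$intensities else as.matrix(tab)
    idx <- match(rownames(x), design$product_id)
    if (anyNA(idx)) stopf("table rows must be named by product id")
    y <- design[[factor_name]][idx]
    cfg_i <- cfg
    cfg_i$n_outer <- min(cfg$n_outer, min(table(y)))
    cfg_i$n_inner <- min(cfg_i$n_inner, max(2L, cfg_i$n_outer - 1L))
    rdcv_select(x, y, cfg_i)
  })
}

#' Predict one sensory attribute from a feature table
#'
#' Regression rdCV of a processed feature table on the per-product sensory
#' response of one attribute (PLS engine for LC-MS-style data, RF for
#' GC-MS-style data, per the study's convention).
#'
#' @param table product-level matrix or processed `feature_table` (rows
#'   named by product id).
#' @param response sensory-response matrix from [sensory_response()].
#' @param attribute attribute (column) name.
#' @param cfg a regression [selection_config()].
#' @return an `rdcv_result`.
#' @export
predict_attribute <- function(table, response, attribute,
                              cfg = selection_config("regression")) {
  x <- if (inherits(table, "feature_table")) table$intensities else
    as.matrix(table)
  if (!attribute %in% colnames(response)) {
    stopf("attribute '%s' not in the sensory response", attribute)
  }
  y <- response[match(rownames(x), rownames(response)), attribute]
  if (anyNA(y)) stopf("response missing for some products in the table")
  if (sd_sample(y) == 0) stopf("attribute '%s' is constant", attribute)
  rdcv_select(x, y, cfg)
}
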