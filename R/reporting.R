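# Result surfaces: attribute-level F vs Q2 summary, top-ranked marker
# tables, cross-platform marker correlations, marker-vs-score scatter data.

#' Join product-effect F values with model Q2 per attribute
#'
#' @param f_results data.frame from [product_f_values()].
#' @param selection_results named list (platform -> named list of
#'   `rdcv_result` per attribute) or a single platform's named list.
#' @param q2_threshold Q2 cut used for the `selected` flag (default 0.3).
#' @return list with `table` (one row per attribute: F, critical_F, Q2 per
#'   platform, `selected` = F above critical and any Q2 above threshold) and
#'   `spearman` (per-platform Spearman rho between F and Q2).
#' @export
attribute_summary <- function(f_results, selection_results,
                              q2_threshold = 0.3) {
  if (length(selection_results) &&
      inherits(selection_results[[1L]], "rdcv_result")) {
    selection_results <- list(model = selection_results)
  }
  tab <- f_results[, c("attribute", "F", "critical_F")]
  for (platform in names(selection_results)) {
    res <- selection_results[[platform]]
    q2 <- vapply(res, function(r) r$performance, numeric(1L))
    col <- paste0("Q2_", platform)
    tab[[col]] <- q2[match(tab$attribute, names(res))]
    only_sel <- setdiff(names(res), tab$attribute)
    if (length(only_sel)) {
      warnf("attribute(s) %s have models but no F value; rows padded",
            paste(only_sel, collapse = ", "))
      pad <- tab[rep(NA_integer_, length(only_sel)), , drop = FALSE]
      pad$attribute <- only_sel
      pad[[col]] <- q2[only_sel]
      tab <- rbind(tab, pad)
    }
  }
  q2_cols <- grep("^Q2_", names(tab), value = TRUE)
  any_q2 <- if (length(q2_cols)) {
    apply(tab[, q2_cols, drop = FALSE], 1L,
          function(v) any(!is.na(v) & v >= q2_threshold))
  } else FALSE
  tab$selected <- !is.na(tab$F) & tab$F > tab$critical_F & any_q2
  spearman <- sapply(q2_cols, function(col) {
    ok <- !is.na(tab$F) & !is.na(tab[[col]])
    if (sum(ok) < 2L) return(NA_real_)
    stats::cor(tab$F[ok], tab[[col]][ok], method = "spearman")
  })
  rownames(tab) <- NULL
  list(table = tab, spearman = spearman)
}

#' Top-ranked features of a selection result
#'
#' @param result an `rdcv_result`.
#' @param n number of features (smallest average rank; ties by feature id).
#' @return data.frame `feature`, `avg_rank`, `position`.
#' @export
top_features <- function(result, n = 5L) {
  stopifnot(inherits(result, "rdcv_result"))
  n <- min(n, nrow(result$ranks))
  if (n == 0L) {
    return(data.frame(feature = character(0), avg_rank = numeric(0),
                      position = integer(0)))
  }
  out <- result$ranks[seq_len(n), , drop = FALSE]
  out$position <- seq_len(n)
  rownames(out) <- NULL
  out
}

#' Cross-platform marker correlations
#'
#' Pearson correlations between selected features of two platforms on
#' matched product-level values (use post-averaging log intensities;
#' correlation is scale-invariant so autoscaling is unnecessary).
#'
#' @param table_a,table_b product-level matrices or `feature_table`s (rows
#'   named by product id).
#' @param set_a,set_b feature ids to pair (e.g. `set_min` of each
#'   platform's `rdcv_result`).
#' @param min_abs_r report only pairs with `|r|` at or above this (default
#'   0.9).
#' @return data.frame `feature_a`, `feature_b`, `r`, `n`, sorted by `|r|`
#'   descending.
#' @export
cross_platform_correlation <- function(table_a, table_b, set_a, set_b,
                                       min_abs_r = 0.9) {
  xa <- if (inherits(table_a, "feature_table")) table_a$intensities else
    as.matrix(table_a)
  xb <- if (inherits(table_b, "feature_table")) table_b$intensities else
    as.matrix(table_b)
  shared <- intersect(rownames(xa), rownames(xb))
  if (length(shared) < 3L) stopf("need >= 3 shared products, got %d",
                                 length(shared))
  set_a <- intersect(set_a, colnames(xa))
  set_b <- intersect(set_b, colnames(xb))
  cm <- stats::cor(xa[shared, set_a, drop = FALSE],
                   xb[shared, set_b, drop = FALSE])
  idx <- which(abs(cm) >= min_abs_r, arr.ind = TRUE)
  out <- data.frame(feature_a = set_a[idx[, 1L]],
                    feature_b = set_b[idx[, 2L]],
                    r = cm[idx],
                    n = rep(length(shared), nrow(idx)),
                    stringsAsFactors = FALSE)
  out <- out[order(-abs(out$r)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Marker-versus-score scatter data
#'
#' Pairs one feature's product-level (log) intensities with one attribute's
#' sensory responses and reports the Pearson correlation, optionally after
#' excluding a product subset (e.g. a flagged yeast arm).
#'
#' @param feature_id feature column in `table`.
#' @param table product-level matrix or `feature_table` (rows named by
#'   product id).
#' @param response sensory-response matrix.
#' @param attribute attribute column in `response`.
#' @param exclude_products product ids excluded before the correlation.
#' @return list with `data` (product, intensity, score), `r`, `n`,
#'   `excluded`, and `degenerate` flag (TRUE when n = 2, where r is forced
#'   to +-1).
#' @export
marker_scatter <- function(feature_id, table, response, attribute,
                           exclude_products = character(0)) {
  x <- if (inherits(table, "feature_table")) table$intensities else
    as.matrix(table)
  if (!feature_id %in% colnames(x)) stopf("feature '%s' not in table",
                                          feature_id)
  if (!attribute %in% colnames(response)) {
    stopf("attribute '%s' not in response", attribute)
  }
  prods <- intersect(rownames(x), rownames(response))
  if (!length(prods)) stopf("no matched products between table and response")
  miss <- setdiff(rownames(x), rownames(response))
  if (length(miss)) stopf("unmatched product(s): %s",
                          paste(utils::head(miss, 3L), collapse = ", "))
  prods <- setdiff(prods, exclude_products)
  if (length(prods) < 2L) stopf("fewer than 2 products after exclusion")
  d <- data.frame(product = prods,
                  intensity = x[prods, feature_id],
                  score = response[prods, attribute],
                  stringsAsFactors = FALSE)
  rownames(d) <- NULL
  list(data = d,
       r = stats::cor(d$intensity, d$score),
       n = nrow(d),
       excluded = exclude_products,
       degenerate = nrow(d) == 2L)
}
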