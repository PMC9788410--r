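# Post-peak-picking preprocessing.  Canonical order:
# blank_filter -> qc_rsd_filter -> log_transform -> average_replicates ->
# autoscale.  Every step appends a record to the table's processing log so
# the pipeline can be replayed bit-for-bit on the raw table.

log_step <- function(t, step, params, removed = character(0)) {
  t$log[[length(t$log) + 1L]] <- list(step = step, params = params,
                                      removed = removed)
  t
}

drop_features <- function(t, ids) {
  if (length(ids)) {
    t$intensities <- t$intensities[, setdiff(colnames(t$intensities), ids),
                                   drop = FALSE]
  }
  t
}

#' Remove features dominated by blank background
#'
#' Drops features whose mean study intensity is below `ratio` times the mean
#' blank intensity — the standard guard against carry-over and solvent
#' background in untargeted metabolomics.
#'
#' @param t a `feature_table`.
#' @param ratio required study/blank mean fold change (default 5).
#' @return filtered `feature_table` with the removal logged.
#' @export
blank_filter <- function(t, ratio = 5) {
  stopifnot(inherits(t, "feature_table"))
  blanks <- t$samples$sample_type == "blank"
  if (!any(blanks)) {
    warnf("no blank samples: blank_filter is a no-op")
    return(log_step(t, "blank_filter", list(ratio = ratio, skipped = TRUE)))
  }
  study <- t$samples$sample_type == "study"
  blank_mean <- colMeans(t$intensities[blanks, , drop = FALSE], na.rm = TRUE)
  study_mean <- colMeans(t$intensities[study, , drop = FALSE], na.rm = TRUE)
  # blank mean 0 never triggers removal, whatever the ratio
  removed <- colnames(t$intensities)[blank_mean > 0 &
                                       study_mean < ratio * blank_mean]
  t <- drop_features(t, removed)
  log_step(t, "blank_filter", list(ratio = ratio), removed)
}

#' Remove features with unstable QC response
#'
#' Drops features whose relative standard deviation (SD/mean) over the
#' pooled-QC injections exceeds `max_rsd`; QC repeatability is the standard
#' per-feature quality gate.
#'
#' @param t a `feature_table`.
#' @param max_rsd maximum tolerated QC RSD as a fraction (default 0.30).
#' @return filtered `feature_table`; with fewer than 3 QC rows the filter is
#'   a no-op with a warning.
#' @export
qc_rsd_filter <- function(t, max_rsd = 0.30) {
  stopifnot(inherits(t, "feature_table"))
  qc <- t$samples$sample_type == "qc"
  if (sum(qc) < 3L) {
    warnf("fewer than 3 QC samples: qc_rsd_filter is a no-op")
    return(log_step(t, "qc_rsd_filter",
                    list(max_rsd = max_rsd, skipped = TRUE)))
  }
  qx <- t$intensities[qc, , drop = FALSE]
  m <- colMeans(qx, na.rm = TRUE)
  s <- apply(qx, 2L, sd_sample)
  rsd <- ifelse(m > 0, s / m, Inf)
  removed <- colnames(t$intensities)[!is.na(rsd) & rsd > max_rsd]
  t <- drop_features(t, removed)
  log_step(t, "qc_rsd_filter", list(max_rsd = max_rsd), removed)
}

#' Natural-log transform intensities
#'
#' Zeros are replaced before logging according to `pseudo_policy`:
#' `"half_min"` (default) substitutes half the smallest positive value of
#' that feature; `"one"` substitutes 1. All-zero features are dropped.
#'
#' @param t a `feature_table`.
#' @param pseudo_policy zero-replacement policy.
#' @return `feature_table` on the natural-log scale.
#' @export
log_transform <- function(t, pseudo_policy = c("half_min", "one")) {
  stopifnot(inherits(t, "feature_table"))
  pseudo_policy <- match.arg(pseudo_policy)
  x <- t$intensities
  removed <- character(0)
  for (f in seq_len(ncol(x))) {
    v <- x[, f]
    pos <- v > 0 & !is.na(v)
    if (!any(pos)) {
      removed <- c(removed, colnames(x)[f])
      next
    }
    if (any(v == 0, na.rm = TRUE)) {
      repl <- switch(pseudo_policy, half_min = min(v[pos]) / 2, one = 1)
      v[v == 0 & !is.na(v)] <- repl
      x[, f] <- v
    }
  }
  if (length(removed)) {
    warnf("dropping %d all-zero feature(s) before log transform",
          length(removed))
    x <- x[, setdiff(colnames(x), removed), drop = FALSE]
  }
  t$intensities <- log(x)
  t <- log_step(t, "log_transform", list(pseudo_policy = pseudo_policy),
                removed)
  t$scale <- "log"
  t
}

#' Average technical replicates
#'
#' Collapses study rows to one row per product by arithmetic mean on the
#' current (log) scale. QC and blank rows are dropped by default once they
#' have served filtering, or passed through with `keep_aux = TRUE`.
#'
#' @param t a `feature_table`.
#' @param keep_aux keep QC/blank rows (default FALSE).
#' @return `feature_table` with one study row per product.
#' @export
average_replicates <- function(t, keep_aux = FALSE) {
  stopifnot(inherits(t, "feature_table"))
  study <- which(t$samples$sample_type == "study")
  prods <- t$samples$product_id[study]
  groups <- split(study, prods)
  avg <- do.call(rbind, lapply(groups, function(rows) {
    colMeans(t$intensities[rows, , drop = FALSE], na.rm = TRUE)
  }))
  colnames(avg) <- colnames(t$intensities)
  # keep first-appearance product order
  avg <- avg[unique(prods), , drop = FALSE]
  meta <- data.frame(sample_id = rownames(avg), product_id = rownames(avg),
                     sample_type = "study", replicate_id = 1L, batch = 1L,
                     injection_order = seq_len(nrow(avg)),
                     stringsAsFactors = FALSE)
  if (keep_aux) {
    aux <- which(t$samples$sample_type != "study")
    if (length(aux)) {
      aux_meta <- t$samples[aux, , drop = FALSE]
      aux_meta$injection_order <- nrow(avg) + seq_along(aux)
      avg <- rbind(avg, t$intensities[aux, , drop = FALSE])
      rownames(avg)[nrow(meta) + seq_along(aux)] <- aux_meta$sample_id
      meta <- rbind(meta, aux_meta)
    }
  }
  t$intensities <- avg
  t$samples <- meta
  log_step(t, "average_replicates", list(keep_aux = keep_aux))
}

#' Autoscale features
#'
#' Per-feature centering and unit-variance (sample SD) scaling — the
#' standard pretreatment before PLS so every feature contributes comparable
#' leverage. Constant features are dropped with a warning.
#'
#' @param t a `feature_table`.
#' @return autoscaled `feature_table`; per-feature centers/scales are kept
#'   in the processing log.
#' @export
autoscale <- function(t) {
  stopifnot(inherits(t, "feature_table"))
  if (nrow(t$intensities) < 2L) stopf("autoscale needs at least 2 rows")
  m <- colMeans(t$intensities, na.rm = TRUE)
  s <- apply(t$intensities, 2L, sd_sample)
  removed <- colnames(t$intensities)[is.na(s) | s == 0]
  if (length(removed)) {
    warnf("dropping %d constant feature(s) in autoscale", length(removed))
    t <- drop_features(t, removed)
    m <- m[setdiff(names(m), removed)]
    s <- s[setdiff(names(s), removed)]
  }
  t$intensities <- sweep(sweep(t$intensities, 2L, m, "-"), 2L, s, "/")
  log_step(t, "autoscale", list(center = m, scale = s), removed)
}

#' Run the canonical preprocessing pipeline
#'
#' blank_filter -> qc_rsd_filter -> log_transform -> average_replicates ->
#' autoscale, with the full processing log attached.
#'
#' @param t a raw `feature_table`.
#' @param blank_ratio study/blank fold-change threshold.
#' @param max_rsd QC RSD threshold.
#' @param pseudo_policy zero-replacement policy for the log transform.
#' @return processed `feature_table` (one autoscaled row per product).
#' @export
preprocess_features <- function(t, blank_ratio = 5, max_rsd = 0.30,
                                pseudo_policy = "half_min") {
  t <- blank_filter(t, blank_ratio)
  t <- qc_rsd_filter(t, max_rsd)
  t <- log_transform(t, pseudo_policy)
  t <- average_replicates(t)
  autoscale(t)
}

#' Replay a processing log on a raw table
#'
#' Re-applies, in order, the steps recorded in another table's processing
#' log. Replaying the log of a processed table on the raw table it came from
#' reproduces it exactly.
#'
#' @param raw a raw `feature_table`.
#' @param log a processing log (`processed$log`).
#' @return reprocessed `feature_table`.
#' @export
replay_log <- function(raw, log) {
  t <- raw
  for (entry in log) {
    t <- switch(entry$step,
                blank_filter = blank_filter(t, entry$params$ratio),
                qc_rsd_filter = qc_rsd_filter(t, entry$params$max_rsd),
                log_transform = log_transform(t, entry$params$pseudo_policy),
                average_replicates =
                  average_replicates(t, entry$params$keep_aux),
                autoscale = autoscale(t),
                stopf("unknown processing step '%s'", entry$step))
  }
  t
}

#' Principal component analysis of a processed table
#'
#' SVD-based PCA (no additional scaling; feed log-scaled or autoscaled
#' data). The sign of each component is fixed so its largest-magnitude
#' loading is positive.
#'
#' @param t a `feature_table` or plain numeric matrix (rows = samples).
#' @param n_components number of components to keep.
#' @return list with `scores`, `loadings`, `explained` (variance fractions,
#'   non-increasing).
#' @export
feature_pca <- function(t, n_components = 2) {
  x <- if (inherits(t, "feature_table")) t$intensities else as.matrix(t)
  x <- x[, colSums(is.na(x)) == 0L, drop = FALSE]
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  r <- length(pc$sdev[pc$sdev > 1e-12])
  if (n_components > r) {
    warnf("n_components reduced to rank %d", r)
    n_components <- r
  }
  keep <- seq_len(n_components)
  load <- pc$rotation[, keep, drop = FALSE]
  sc <- pc$x[, keep, drop = FALSE]
  for (a in keep) {
    if (load[which.max(abs(load[, a])), a] < 0) {
      load[, a] <- -load[, a]
      sc[, a] <- -sc[, a]
    }
  }
  list(scores = sc, loadings = load,
       explained = (pc$sdev^2 / sum(pc$sdev^2))[keep])
}
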