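# Panel-score standardization and product-effect F statistics.
#
# Standardization removes per-assessor offset and scale one attribute at a
# time: ytilde_ijk = (y_ijk - mean_ik) / sd_ik, then a back-transform
# restores the attribute-level mean and a pooled SD so scores stay readable
# in the original units. The per-product sensory response nu_jk is the mean
# of back-transformed scores across assessors and is the downstream
# regression target.

#' Standardize panel scores per assessor and attribute
#'
#' For each (assessor, attribute) slice, centers by the assessor's mean over
#' products and divides by the assessor's sample SD, so each retained slice
#' has mean 0 and SD 1. Constant slices (SD 0) carry no product information
#' and are dropped with a warning (or rejected when
#' `on_constant = "error"`).
#'
#' @param scores a [panel_scores()] tensor (or plain 3-d array indexed
#'   assessor x product x attribute).
#' @param on_constant "drop" (default) or "error" for constant slices.
#' @return list with `z` (standardized tensor) and `stats` (a
#'   `standardization_stats` list: `mean_ik`, `sd_ik`, `mean_k`, and slots
#'   for the pooled SD filled by [pooled_sd()]).
#' @export
standardize_scores <- function(scores, on_constant = c("drop", "error")) {
  on_constant <- match.arg(on_constant)
  y <- unclass(scores)
  stopifnot(length(dim(y)) == 3L)
  I <- dim(y)[1L]; K <- dim(y)[3L]
  mean_ik <- matrix(NA_real_, I, K,
                    dimnames = dimnames(y)[c(1L, 3L)])
  sd_ik <- mean_ik
  z <- y
  for (k in seq_len(K)) {
    for (i in seq_len(I)) {
      v <- y[i, , k]
      obs <- !is.na(v)
      if (sum(obs) < 2L) {
        z[i, , k] <- NA_real_
        next
      }
      m <- mean(v[obs]); s <- sd_sample(v)
      if (is.na(s) || s == 0) {
        if (on_constant == "error") {
          stopf("constant scores for assessor '%s', attribute '%s'",
                dimnames(y)[[1L]][i], dimnames(y)[[3L]][k])
        }
        warnf("dropping constant slice: assessor '%s', attribute '%s'",
              dimnames(y)[[1L]][i], dimnames(y)[[3L]][k])
        z[i, , k] <- NA_real_
        next
      }
      mean_ik[i, k] <- m
      sd_ik[i, k] <- s
      z[i, , k] <- (v - m) / s
    }
  }
  mean_k <- apply(y, 3L, function(sl) mean(sl, na.rm = TRUE))
  stats <- structure(list(mean_ik = mean_ik, sd_ik = sd_ik, mean_k = mean_k,
                          pooled = NULL, pooled_mode = NULL),
                     class = "standardization_stats")
  list(z = z, stats = stats)
}

#' Pooled per-attribute standard deviation
#'
#' Two modes. `"conventional"` (default) is the root mean of the per-assessor
#' variances, `sqrt(sum_i sd_ik^2 / I)` — the form that actually restores the
#' attribute-level spread on back-transformation. `"literal"` is
#' `sum_i sd_ik / (I * (J - 1))`, the arithmetic form sometimes printed in
#' QDA write-ups; it is dimensionally a shrunken mean SD (smaller by roughly
#' 1/(J-1)) and is provided for fidelity comparisons only.
#'
#' @param stats `standardization_stats` from [standardize_scores()].
#' @param n_products J, the number of products (needed by the literal mode).
#' @param mode "conventional" or "literal".
#' @return the `stats` object with `pooled` (named per-attribute vector) and
#'   `pooled_mode` filled in.
#' @export
pooled_sd <- function(stats, n_products,
                      mode = c("conventional", "literal")) {
  mode <- match.arg(mode)
  stopifnot(inherits(stats, "standardization_stats"))
  sp <- apply(stats$sd_ik, 2L, function(s) {
    s <- s[!is.na(s)]
    if (!length(s)) stopf("no retained assessors for an attribute")
    switch(mode,
           conventional = sqrt(sum(s^2) / length(s)),
           literal = sum(s) / (length(s) * (n_products - 1)))
  })
  stats$pooled <- sp
  stats$pooled_mode <- mode
  stats
}

#' Back-transform standardized scores to interpretable units
#'
#' `ystar_ijk = mean_k + z_ijk * sp_k`: restores the attribute's overall
#' mean and the pooled spread while keeping every assessor on a common
#' scale.
#'
#' @param z standardized tensor from [standardize_scores()].
#' @param stats `standardization_stats` with the pooled SD filled in (see
#'   [pooled_sd()]).
#' @return tensor of back-transformed scores, same shape as `z`.
#' @export
back_transform <- function(z, stats) {
  stopifnot(inherits(stats, "standardization_stats"))
  if (is.null(stats$pooled)) stopf("run pooled_sd() before back_transform()")
  out <- unclass(z)
  for (k in seq_len(dim(out)[3L])) {
    out[, , k] <- stats$mean_k[k] + out[, , k] * stats$pooled[k]
  }
  out
}

#' Per-product sensory responses
#'
#' The sensory response `nu_jk` is the mean across assessors of the
#' back-transformed standardized scores, one value per (product, attribute).
#'
#' @param ystar back-transformed tensor from [back_transform()] (any
#'   assessor x product x attribute tensor works).
#' @return numeric matrix `[product, attribute]`; a cell with zero assessors
#'   is NA with a warning.
#' @export
sensory_response <- function(ystar) {
  y <- unclass(ystar)
  stopifnot(length(dim(y)) == 3L)
  nu <- apply(y, c(2L, 3L), function(v) {
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  })
  if (anyNA(nu)) {
    warnf("%d (product, attribute) cell(s) have no assessors; responses NA",
          sum(is.na(nu)))
  }
  nu
}

#' Product-effect F statistics per attribute
#'
#' Fits, per attribute, a linear mixed model with product as a fixed effect
#' and assessor as a random intercept (REML, Satterthwaite denominator df)
#' and reports the product-effect F alongside the critical F at level
#' `alpha`. For a complete balanced panel this equals the classical two-way
#' (product + assessor blocks) ANOVA F.
#'
#' @param scores assessor x product x attribute tensor (raw or
#'   standardized/back-transformed; the statistic applies to either).
#' @param alpha significance level for the critical F (default 0.05).
#' @return data.frame with columns `attribute`, `F`, `df_num`, `df_den`,
#'   `p_value`, `critical_F`. Attributes with insufficient replication are
#'   skipped with a warning.
#' @export
product_f_values <- function(scores, alpha = 0.05) {
  y <- unclass(scores)
  stopifnot(length(dim(y)) == 3L)
  dn <- dimnames(y)
  out <- vector("list", dim(y)[3L])
  for (k in seq_len(dim(y)[3L])) {
    sl <- y[, , k, drop = FALSE]
    df <- data.frame(
      score = as.vector(sl),
      assessor = factor(rep(dn[[1L]], times = dim(y)[2L])),
      product = factor(rep(dn[[2L]], each = dim(y)[1L])))
    df <- df[!is.na(df$score), , drop = FALSE]
    if (nlevels(droplevels(df$product)) < 2L ||
        nlevels(droplevels(df$assessor)) < 2L ||
        nrow(df) <= nlevels(droplevels(df$product)) +
          nlevels(droplevels(df$assessor))) {
      warnf("attribute '%s' skipped: insufficient replication", dn[[3L]][k])
      next
    }
    df$product <- droplevels(df$product)
    df$assessor <- droplevels(df$assessor)
    fit <- suppressMessages(suppressWarnings(
      lmerTest::lmer(score ~ product + (1 | assessor), data = df,
                     REML = TRUE)))
    an <- suppressWarnings(stats::anova(fit, type = 3))
    Fv <- an["product", "F value"]
    df1 <- an["product", "NumDF"]
    df2 <- an["product", "DenDF"]
    out[[k]] <- data.frame(attribute = dn[[3L]][k], F = Fv,
                           df_num = df1, df_den = df2,
                           p_value = stats::pf(Fv, df1, df2,
                                               lower.tail = FALSE),
                           critical_F = stats::qf(1 - alpha, df1, df2),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
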