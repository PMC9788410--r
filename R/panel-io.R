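# Panel score container and long-CSV I/O.
#
# Scores live in a 3-d array indexed (assessor, product, attribute) with NA
# for cells a pair never assessed.  Session replicates are averaged into the
# tensor at load time (the downstream model indexes scores by assessor,
# product and attribute only); the raw long table is kept as an attribute so
# writing round-trips exactly.

#' Construct a panel-score tensor from a long table
#'
#' @param long data.frame with columns `assessor_id`, `session`,
#'   `product_id`, `attribute`, `score` (0-100 scale).
#' @return a `panel_scores` object: a 3-d array `[assessor, product,
#'   attribute]` of session-averaged scores, with the validated long table
#'   kept in `attr(, "long")`.
#' @export
panel_scores <- function(long) {
  long <- as.data.frame(long, stringsAsFactors = FALSE)
  need <- c("assessor_id", "session", "product_id", "attribute", "score")
  missing_cols <- setdiff(need, names(long))
  if (length(missing_cols)) {
    stopf("panel scores missing column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  long$score <- as.numeric(long$score)
  bad <- which(is.na(long$score) | long$score < 0 | long$score > 100)
  if (length(bad)) {
    stopf("score out of [0, 100] at row %d (value %s)", bad[1L],
          format(long$score[bad[1L]]))
  }
  key <- paste(long$assessor_id, long$session, long$product_id, long$attribute,
               sep = "\r")
  if (anyDuplicated(key)) {
    d <- which(duplicated(key))[1L]
    stopf("duplicate (assessor, session, product, attribute) record at row %d: %s/%s/%s/%s",
          d, long$assessor_id[d], long$session[d], long$product_id[d],
          long$attribute[d])
  }
  assessors <- unique(as.character(long$assessor_id))
  products  <- unique(as.character(long$product_id))
  attributes <- unique(as.character(long$attribute))
  arr <- array(NA_real_,
               dim = c(length(assessors), length(products), length(attributes)),
               dimnames = list(assessor = assessors, product = products,
                               attribute = attributes))
  i <- match(as.character(long$assessor_id), assessors)
  j <- match(as.character(long$product_id), products)
  k <- match(as.character(long$attribute), attributes)
  # linear cell index; average session replicates per cell
  li <- i + (j - 1L) * length(assessors) +
    (k - 1L) * length(assessors) * length(products)
  means <- tapply(long$score, li, mean)
  arr[as.integer(names(means))] <- as.numeric(means)
  structure(arr, long = long, n_sessions = length(unique(long$session)),
            class = c("panel_scores", "array"))
}

#' Read panel scores from a long CSV
#'
#' @param path long-format CSV: one row per (assessor, session, product,
#'   attribute) score.
#' @return a [panel_scores()] tensor.
#' @export
load_panel_scores <- function(path) {
  panel_scores(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write panel scores back to long CSV
#'
#' @param scores a `panel_scores` object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_panel_scores <- function(scores, path) {
  stopifnot(inherits(scores, "panel_scores"))
  long <- attr(scores, "long")
  long$score <- sprintf("%.17g", long$score)  # bit-exact round trip
  utils::write.csv(long, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.panel_scores <- function(x, ...) {
  d <- dim(x)
  n_missing <- sum(is.na(x))
  cat(sprintf("Panel scores: %d assessors x %d products x %d attributes\n",
              d[1L], d[2L], d[3L]))
  cat(sprintf("  sessions: %d; missing cells: %d of %d (%.1f%%)\n",
              attr(x, "n_sessions"), n_missing, prod(d),
              100 * n_missing / prod(d)))
  invisible(x)
}
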