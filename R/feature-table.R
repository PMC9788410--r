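# Feature-table container: samples x features intensity matrix plus sample
# metadata (product, sample type, replicate, batch, injection order).

.sample_meta_cols <- c("sample_id", "product_id", "sample_type",
                       "replicate_id", "batch", "injection_order")

validate_sample_meta <- function(meta, design = NULL) {
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.sample_meta_cols, names(meta))
  if (length(missing_cols)) {
    stopf("sample metadata missing column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  meta$sample_id <- as.character(meta$sample_id)
  meta$product_id <- as.character(meta$product_id)
  meta$product_id[meta$product_id %in% c("", "NA")] <- NA_character_
  meta$sample_type <- as.character(meta$sample_type)
  bad <- which(!meta$sample_type %in% c("study", "qc", "blank"))
  if (length(bad)) {
    stopf("unknown sample_type '%s' at metadata row %d",
          meta$sample_type[bad[1L]], bad[1L])
  }
  for (col in c("replicate_id", "batch", "injection_order")) {
    meta[[col]] <- as.integer(meta[[col]])
    if (any(is.na(meta[[col]])) || any(meta[[col]] < 1L)) {
      stopf("column '%s' must be integer >= 1", col)
    }
  }
  if (anyDuplicated(meta$sample_id)) stopf("duplicate sample_id in metadata")
  dup_inj <- meta[duplicated(meta[, c("batch", "injection_order")]), , drop = FALSE]
  if (nrow(dup_inj)) {
    stopf("injection_order %d duplicated within batch %d",
          dup_inj$injection_order[1L], dup_inj$batch[1L])
  }
  no_prod <- which(meta$sample_type == "study" & is.na(meta$product_id))
  if (length(no_prod)) {
    stopf("study sample '%s' has no product_id", meta$sample_id[no_prod[1L]])
  }
  if (!is.null(design)) {
    unknown <- setdiff(stats::na.omit(meta$product_id), design$product_id)
    if (length(unknown)) {
      stopf("sample metadata references unknown product_id: %s",
            paste(unknown, collapse = ", "))
    }
  }
  meta
}

#' Construct a feature table
#'
#' @param intensities numeric samples x features matrix (row names =
#'   sample ids, column names = feature ids); values are nonnegative peak
#'   intensities or NA for missing.
#' @param sample_meta data.frame of per-sample metadata (`sample_id`,
#'   `product_id`, `sample_type` in study/qc/blank, `replicate_id`, `batch`,
#'   `injection_order`).
#' @param platform platform label, e.g. "lcms" or "gcms".
#' @param design optional `study_design` used to validate product references.
#' @return a `feature_table` object.
#' @export
feature_table <- function(intensities, sample_meta, platform = "lcms",
                          design = NULL) {
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  meta <- validate_sample_meta(sample_meta, design)
  if (is.null(rownames(intensities))) {
    stopf("intensity matrix must carry sample ids as row names")
  }
  missing_meta <- setdiff(rownames(intensities), meta$sample_id)
  if (length(missing_meta)) {
    stopf("sample '%s' present in intensities but absent from metadata",
          missing_meta[1L])
  }
  meta <- meta[match(rownames(intensities), meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  if (any(intensities < 0, na.rm = TRUE)) {
    stopf("negative intensity found (feature '%s')",
          colnames(intensities)[which(colSums(intensities < 0, na.rm = TRUE) > 0)[1L]])
  }
  if (is.null(colnames(intensities))) {
    colnames(intensities) <- sprintf("F%04d", seq_len(ncol(intensities)))
  }
  if (anyDuplicated(colnames(intensities))) stopf("duplicate feature ids")
  all_na <- which(colSums(!is.na(intensities)) == 0L)
  if (length(all_na)) {
    warnf("dropping %d all-missing feature column(s): %s", length(all_na),
          paste(utils::head(colnames(intensities)[all_na], 5L), collapse = ", "))
    intensities <- intensities[, -all_na, drop = FALSE]
  }
  structure(list(intensities = intensities, samples = meta,
                 platform = platform, log = list()),
            class = "feature_table")
}

#' Read a feature table from intensity + metadata CSVs
#'
#' @param path intensity CSV: first column `sample_id`, remaining columns one
#'   per feature; empty cells are missing (not zero).
#' @param meta_path CSV of sample metadata.
#' @param platform platform label stored on the table.
#' @param design optional `study_design` for product validation.
#' @return a [feature_table()].
#' @export
load_feature_table <- function(path, meta_path, platform = "lcms",
                               design = NULL) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(raw)[1L] != "sample_id") {
    stopf("first column of '%s' must be sample_id", path)
  }
  mat <- as.matrix(raw[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- as.character(raw$sample_id)
  meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
  feature_table(mat, meta, platform = platform, design = design)
}

#' Write a feature table to intensity + metadata CSVs
#'
#' @param t a `feature_table`.
#' @param path output intensity CSV path.
#' @param meta_path output metadata CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(t, path, meta_path) {
  stopifnot(inherits(t, "feature_table"))
  # 17 significant digits so doubles round-trip bit-exactly
  chr <- apply(t$intensities, 2L, function(v)
    ifelse(is.na(v), "", sprintf("%.17g", v)))
  df <- data.frame(sample_id = rownames(t$intensities),
                   chr, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  utils::write.csv(t$samples, meta_path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}

#' @export
print.feature_table <- function(x, ...) {
  tab <- table(factor(x$samples$sample_type,
                      levels = c("study", "qc", "blank")))
  cat(sprintf("Feature table [%s]: %d samples x %d features\n", x$platform,
              nrow(x$intensities), ncol(x$intensities)))
  cat(sprintf("  study: %d, qc: %d, blank: %d; processing steps applied: %d\n",
              tab[["study"]], tab[["qc"]], tab[["blank"]], length(x$log)))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$intensities)
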