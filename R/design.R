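# Study-design data model: product compositions over five factors.

.design_cols <- c("product_id", "oil_type", "tomato_dose", "yeast_product",
                  "yeast_dose", "heat")

.factor_levels <- list(
  oil_type    = c("corn", "olive"),
  tomato_dose = c("high", "low"),
  yeast_dose  = c("none", "low", "high"),
  heat        = c("short", "long")
)

#' Construct a validated study design
#'
#' A study design is a table of product compositions over five factors:
#' oil type (corn/olive), tomato dosage (high/low), yeast-derived flavor
#' product (a product code or "none"), yeast dosage (none/low/high) and
#' heating duration (short/long).
#'
#' @param df data.frame with columns `product_id`, `oil_type`, `tomato_dose`,
#'   `yeast_product`, `yeast_dose`, `heat`.
#' @return a `study_design` object (a validated data.frame, row order kept).
#' @export
study_design <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.design_cols, names(df))
  if (length(missing_cols)) {
    stopf("design is missing column(s): %s", paste(missing_cols, collapse = ", "))
  }
  df <- df[, .design_cols]
  for (col in .design_cols) df[[col]] <- as.character(df[[col]])
  if (nrow(df)) {
    if (any(!nzchar(df$product_id))) stopf("empty product_id in design")
    dup <- df$product_id[duplicated(df$product_id)]
    if (length(dup)) stopf("duplicate product_id in design: %s",
                           paste(unique(dup), collapse = ", "))
    for (col in names(.factor_levels)) {
      bad <- which(!df[[col]] %in% .factor_levels[[col]])
      if (length(bad)) {
        stopf("unknown level '%s' for factor '%s' (row %d)",
              df[[col]][bad[1L]], col, bad[1L])
      }
    }
    mism <- which((df$yeast_product == "none") != (df$yeast_dose == "none"))
    if (length(mism)) {
      stopf("yeast_product/yeast_dose none-mismatch at row %d (product '%s')",
            mism[1L], df$product_id[mism[1L]])
    }
  } else {
    warnf("study design has zero products")
  }
  rownames(df) <- NULL
  class(df) <- c("study_design", "data.frame")
  df
}

#' Read a study design from CSV
#'
#' @param path CSV file with a header row matching the design columns.
#' @return a [study_design()] object.
#' @export
load_design <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = "character")
  study_design(df)
}

#' Write a study design to CSV
#'
#' @param design a `study_design`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "study_design"))
  utils::write.csv(as.data.frame(design), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' The default 27-product design
#'
#' Nine yeast arms (four yeast product codes x two doses, plus a no-yeast
#' BLK arm) crossed with three soup-base variants over oil type, tomato
#' dosage and heating, giving 27 products. The cell-by-cell table is a
#' synthetic stand-in consistent with the stated factor structure; replace
#' it via [load_design()] for a real study.
#'
#' @return a `study_design` with 27 products.
#' @export
default_design <- function() {
  load_design(system.file("extdata", "design_default.csv",
                          package = "flavorlink", mustWork = TRUE))
}

#' The default 26 sensory attribute names
#'
#' QDA attributes across odor, flavor, mouthfeel, aftertaste and afterfeel,
#' using the conventional suffixes `.od`, `.fl`, `.mf`, `.at`, `.af`.
#'
#' @return character vector of 26 attribute names.
#' @export
default_attributes <- function() {
  c("intensity.od", "tomato.od", "garlic.od", "onion.od", "yeast.od",
    "sour.od",
    "intensity.fl", "tomato.fl", "garlic.fl", "onion.fl", "umami.fl",
    "sweet.fl", "bitter.fl", "salty.fl", "sour.fl", "yeast.fl",
    "thickness.mf", "mouthfullness.mf", "creamy.mf", "watery.mf",
    "intensity.at", "umami.at", "bitter.at", "salty.at",
    "coating.af", "drying.af")
}
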