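# Small in-code fixtures shared across test files.

# a minimal valid design with n products cycling through all factor levels
toy_design <- function(n = 6L) {
  yeast <- rep(c("S99", "G28", "none"), length.out = n)
  study_design(data.frame(
    product_id = sprintf("P%02d", seq_len(n)),
    oil_type = rep(c("corn", "olive"), length.out = n),
    tomato_dose = rep(c("high", "low"), length.out = n),
    yeast_product = yeast,
    yeast_dose = ifelse(yeast == "none", "none",
                        rep(c("low", "high"), length.out = n)),
    heat = rep(c("short", "long"), length.out = n),
    stringsAsFactors = FALSE))
}

# long-format score rows for a complete single-session panel
toy_panel_long <- function(scores, assessors = NULL, products = NULL,
                           attribute = "umami.fl") {
  # scores: matrix assessor x product
  if (is.null(assessors)) assessors <- sprintf("A%02d", seq_len(nrow(scores)))
  if (is.null(products)) products <- sprintf("P%02d", seq_len(ncol(scores)))
  data.frame(
    assessor_id = rep(assessors, times = ncol(scores)),
    session = 1L,
    product_id = rep(products, each = nrow(scores)),
    attribute = attribute,
    score = as.vector(scores),
    stringsAsFactors = FALSE)
}

# a small effect map with one driven and one flat attribute
toy_effect_map <- function() {
  effect_map(
    data.frame(attribute = c("tomato.fl", "garlic.fl"),
               factor = c("tomato_dose", "yeast_product"),
               level = c("high", "G28"),
               effect = c(15, 20), stringsAsFactors = FALSE),
    baselines = c(tomato.fl = 40, garlic.fl = 30, drying.af = 45))
}

# tiny feature table: counts chosen so blank/qc filters are exercised
toy_feature_table <- function() {
  ids <- c(sprintf("S%02d", 1:6), "QC1", "QC2", "QC3", "B1")
  x <- matrix(100, 10, 4,
              dimnames = list(ids, c("keep", "blanky", "noisyqc", "flat")))
  x[, "keep"] <- c(10, 20, 30, 40, 50, 60, 35, 36, 34, 0.1)
  x[, "blanky"] <- c(100, 110, 90, 105, 95, 100, 100, 100, 100, 100)
  x[, "noisyqc"] <- c(80, 90, 100, 110, 120, 100, 50, 100, 150, 0.1)
  x[, "flat"] <- c(rep(70, 6), 70, 70, 70, 0.1)
  meta <- data.frame(
    sample_id = ids,
    product_id = c(rep(sprintf("P%02d", 1:3), each = 2), NA, NA, NA, NA),
    sample_type = c(rep("study", 6), rep("qc", 3), "blank"),
    replicate_id = c(rep(1:2, 3), 1:3, 1),
    batch = 1L,
    injection_order = 1:10,
    stringsAsFactors = FALSE)
  feature_table(x, meta, platform = "lcms")
}

expect_no_na <- function(x) expect_false(anyNA(x))
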