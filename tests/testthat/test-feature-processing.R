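# Preprocessing: blank/QC filters, log transform, replicate averaging,
# autoscaling, PCA, and processing-log replay.

test_that("blank filter removes background features and spares absent ones", {
  ft <- toy_feature_table()
  out <- blank_filter(ft, ratio = 5)
  # 'blanky': blank mean 100, study mean 100 -> removed at ratio 5
  expect_false("blanky" %in% colnames(out$intensities))
  # 'keep': blank intensity 0.1, study mean 35 -> ratio 350, retained
  expect_true("keep" %in% colnames(out$intensities))

  # blank mean exactly 0 is retained for any ratio
  x <- matrix(c(5, 5, 0), 3, 1, dimnames = list(c("S1", "S2", "B1"), "f"))
  meta <- data.frame(sample_id = c("S1", "S2", "B1"),
                     product_id = c("P1", "P2", NA),
                     sample_type = c("study", "study", "blank"),
                     replicate_id = 1L, batch = 1L, injection_order = 1:3)
  t0 <- feature_table(x, meta)
  expect_true("f" %in% colnames(blank_filter(t0, 1e6)$intensities))
})

test_that("planted blank-background features are removed exactly", {
  d <- toy_design(6)
  cfg <- platform_sim_config("lcms", n_features = 100,
                             n_markers_per_attribute = 2,
                             n_background_features = 20, n_qc = 3,
                             seed = 33)
  sim <- simulate_feature_table(d, toy_effect_map(), cfg)
  out <- blank_filter(sim$table, ratio = 5)
  removed <- setdiff(colnames(sim$table$intensities),
                     colnames(out$intensities))
  expect_setequal(removed, sim$truth$background_features)
})

test_that("QC RSD filter drops unstable features per the RSD formula", {
  ft <- toy_feature_table()
  # 'noisyqc' QC = {50,100,150}: RSD = 0.5 -> removed at 0.3
  out <- qc_rsd_filter(ft, max_rsd = 0.3)
  expect_false("noisyqc" %in% colnames(out$intensities))
  # constant QC response (RSD 0) retained
  expect_true("flat" %in% colnames(out$intensities))
  # infinite threshold is the identity
  out2 <- qc_rsd_filter(ft, max_rsd = Inf)
  expect_equal(colnames(out2$intensities), colnames(ft$intensities))
  # fewer than 3 QCs: warning no-op
  sub <- ft
  keep_rows <- ft$samples$sample_type != "qc"
  sub$intensities <- ft$intensities[keep_rows, , drop = FALSE]
  sub$samples <- ft$samples[keep_rows, , drop = FALSE]
  expect_warning(out3 <- qc_rsd_filter(sub, 0.3), "fewer than 3 QC")
  expect_equal(colnames(out3$intensities), colnames(ft$intensities))
})

test_that("log transform uses natural log with the half-minimum zero policy", {
  x <- matrix(c(1, exp(1), 0, 10), 2, 2,
              dimnames = list(c("S1", "S2"), c("f1", "f2")))
  meta <- data.frame(sample_id = c("S1", "S2"), product_id = c("P1", "P2"),
                     sample_type = "study", replicate_id = 1L, batch = 1L,
                     injection_order = 1:2)
  t0 <- feature_table(x, meta)
  out <- log_transform(t0)
  expect_equal(out$intensities[, "f1"], c(S1 = 0, S2 = 1))
  expect_equal(out$intensities[, "f2"], c(S1 = log(5), S2 = log(10)))
})

test_that("replicate averaging means on the current scale; identity cases", {
  x <- matrix(exp(c(2, 4, 3)), 3, 1,
              dimnames = list(c("S1", "S2", "S3"), "f"))
  meta <- data.frame(sample_id = c("S1", "S2", "S3"),
                     product_id = c("P1", "P1", "P2"),
                     sample_type = "study",
                     replicate_id = c(1L, 2L, 1L), batch = 1L,
                     injection_order = 1:3)
  out <- average_replicates(log_transform(feature_table(x, meta)))
  expect_equal(out$intensities["P1", "f"], 3)   # mean of log 2 and 4
  expect_equal(out$intensities["P2", "f"], 3)   # single replicate unchanged
  expect_equal(nrow(out$intensities), 2L)

  # noiseless quadruplicates: averaging equals any single replicate
  sim <- simulate_feature_table(toy_design(6), toy_effect_map(),
                                platform_sim_config(n_features = 20,
                                                    n_markers_per_attribute = 1,
                                                    technical_cv = 0,
                                                    n_tech_replicates = 4,
                                                    n_replicated_samples = 6,
                                                    n_qc = 3,
                                                    n_background_features = 2,
                                                    seed = 3))
  lg <- log_transform(sim$table)
  avg <- average_replicates(lg)
  one <- lg$intensities[lg$samples$sample_type == "study" &
                          lg$samples$replicate_id == 1, , drop = FALSE]
  rownames(one) <- lg$samples$product_id[lg$samples$sample_type == "study" &
                                           lg$samples$replicate_id == 1]
  expect_equal(avg$intensities, one[rownames(avg$intensities), ],
               tolerance = 1e-12)
})

test_that("autoscaling gives unit columns, is idempotent, drops constants", {
  x <- matrix(c(1, 3, 5, 5), 2, 2,
              dimnames = list(c("P1", "P2"), c("f1", "const")))
  meta <- data.frame(sample_id = c("P1", "P2"), product_id = c("P1", "P2"),
                     sample_type = "study", replicate_id = 1L, batch = 1L,
                     injection_order = 1:2)
  expect_warning(out <- autoscale(feature_table(x, meta)), "constant")
  expect_equal(unname(out$intensities[, "f1"]), c(-0.7071, 0.7071),
               tolerance = 1e-4)
  expect_false("const" %in% colnames(out$intensities))

  sim <- simulate_feature_table(toy_design(6), toy_effect_map(),
                                platform_sim_config(n_features = 30,
                                                    n_markers_per_attribute = 2,
                                                    n_qc = 3,
                                                    n_background_features = 0,
                                                    seed = 9))
  proc <- preprocess_features(sim$table)
  expect_lt(max(abs(colMeans(proc$intensities))), 1e-10)
  expect_lt(max(abs(apply(proc$intensities, 2, sd) - 1)), 1e-10)
  again <- autoscale(proc)
  expect_equal(again$intensities, proc$intensities, tolerance = 1e-10)
})

test_that("replaying the processing log reproduces the processed table", {
  sim <- simulate_feature_table(toy_design(6), toy_effect_map(),
                                platform_sim_config(n_features = 50,
                                                    n_markers_per_attribute = 2,
                                                    n_qc = 4,
                                                    n_background_features = 5,
                                                    seed = 13))
  proc <- preprocess_features(sim$table, blank_ratio = 5, max_rsd = 0.3)
  replayed <- replay_log(sim$table, proc$log)
  expect_identical(replayed$intensities, proc$intensities)
  expect_equal(length(proc$log), 5L)
})

test_that("PCA: rank-1 limit, reconstruction identity, sign convention", {
  u <- c(1, 2, 3, 4); v <- c(2, -1, 0.5)
  x <- u %*% t(v)
  rownames(x) <- sprintf("S%d", 1:4); colnames(x) <- sprintf("f%d", 1:3)
  expect_warning(pc <- feature_pca(x, n_components = 3), "rank")
  expect_equal(pc$explained[1], 1, tolerance = 1e-12)

  set.seed(14)
  x2 <- matrix(rnorm(6 * 4), 6, 4)
  pc2 <- feature_pca(x2, n_components = 4)
  recon <- pc2$scores %*% t(pc2$loadings)
  expect_equal(recon, unname(scale(x2, scale = FALSE)), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_true(all(diff(pc2$explained) <= 1e-12))
  expect_lte(sum(pc2$explained), 1 + 1e-12)
  for (a in 1:4) {
    expect_gt(pc2$loadings[which.max(abs(pc2$loadings[, a])), a], 0)
  }
})

test_that("dominant tomato-dose effect separates groups along PC1", {
  d <- default_design()
  em <- effect_map(data.frame(attribute = "tomato.fl", factor = "tomato_dose",
                              level = "high", effect = 20),
                   baselines = c(tomato.fl = 40))
  cfg <- platform_sim_config("lcms", n_features = 80,
                             n_markers_per_attribute = 25,
                             marker_effect = 2, technical_cv = 0.02,
                             n_replicated_samples = 0, n_qc = 3,
                             n_background_features = 0, seed = 44)
  sim <- simulate_feature_table(d, em, cfg)
  proc <- preprocess_features(sim$table)
  pc <- feature_pca(proc, 2)
  hi <- pc$scores[d$product_id[d$tomato_dose == "high"], 1]
  lo <- pc$scores[d$product_id[d$tomato_dose == "low"], 1]
  expect_true(min(hi) > max(lo) || min(lo) > max(hi))
})
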