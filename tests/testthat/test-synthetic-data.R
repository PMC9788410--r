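# Generator properties: determinism, noiseless limits, planted structure.

test_that("panel generator is deterministic and respects noiseless limit", {
  d <- toy_design(6)
  em <- toy_effect_map()
  cfg0 <- panel_sim_config(n_assessors = 4, n_sessions = 2,
                           assessor_offset_sd = 0, assessor_scale_sd = 0,
                           noise_sd = 0, seed = 3)
  a <- simulate_panel(d, em, cfg0)
  b <- simulate_panel(d, em, cfg0)
  expect_identical(unclass(a$scores), unclass(b$scores))

  # noiseless limit: every assessor reports exactly mu
  mu <- true_response(d, em)
  for (i in 1:4) {
    expect_equal(unname(unclass(a$scores)[i, , ]), unname(mu),
                 tolerance = 1e-12)
  }
  expect_equal(a$truth$clip_fraction, 0)
})

test_that("assessor offsets shift raw means but cancel under standardization", {
  d <- toy_design(8)
  cfg <- panel_sim_config(n_assessors = 5, n_sessions = 1,
                          assessor_offset_sd = 10, assessor_scale_sd = 0,
                          noise_sd = 0, seed = 11)
  sim <- simulate_panel(d, toy_effect_map(), cfg)
  y <- unclass(sim$scores)
  raw_means <- apply(y[, , "tomato.fl"], 1L, mean)
  expect_gt(sd(raw_means), 0.5)  # offsets visible in raw scores
  # the flat attribute is constant at zero noise; its slice drop is the
  # documented behavior tested elsewhere
  z <- suppressWarnings(standardize_scores(sim$scores))$z
  # after per-assessor standardization all assessors agree exactly
  for (i in 2:5) {
    expect_equal(z[i, , "tomato.fl"], z[1, , "tomato.fl"],
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("feature generator: replicates identical at zero technical noise", {
  d <- toy_design(6)
  cfg <- platform_sim_config("lcms", n_features = 30,
                             n_markers_per_attribute = 2, technical_cv = 0,
                             n_tech_replicates = 3, n_replicated_samples = 2,
                             n_qc = 3, n_background_features = 4, seed = 5)
  sim <- simulate_feature_table(d, toy_effect_map(), cfg)
  tab <- sim$table
  reps <- tab$intensities[tab$samples$product_id %in% "P01" &
                            tab$samples$sample_type %in% "study", ,
                          drop = FALSE]
  expect_equal(nrow(reps), 3L)
  expect_equal(reps[2, ], reps[1, ], tolerance = 1e-12)
  expect_equal(reps[3, ], reps[1, ], tolerance = 1e-12)
  # QC rows are the pooled mean: identical to each other at cv = 0
  qcs <- tab$intensities[tab$samples$sample_type == "qc", , drop = FALSE]
  expect_equal(qcs[2, ], qcs[1, ], tolerance = 1e-12)
})

test_that("marker budget overflow errors; QC spacing interleaves QCs", {
  d <- toy_design(6)
  expect_error(
    simulate_feature_table(d, toy_effect_map(),
                           platform_sim_config(n_features = 8,
                                               n_markers_per_attribute = 3,
                                               n_background_features = 0)),
    "marker budget")
  cfg <- platform_sim_config("gcms", n_features = 30,
                             n_markers_per_attribute = 1, n_qc = 4,
                             qc_spacing = 3, n_background_features = 2,
                             n_replicated_samples = 0, seed = 2)
  sim <- simulate_feature_table(d, toy_effect_map(), cfg)
  meta <- sim$table$samples
  qc_pos <- meta$injection_order[meta$sample_type == "qc"]
  expect_equal(length(qc_pos), 4L)
  study_pos <- meta$injection_order[meta$sample_type == "study"]
  # a QC precedes the first study injection and recurs within every
  # qc_spacing-long study stretch
  expect_lt(qc_pos[1], min(study_pos))
})

test_that("null marker effect gives calibrated ANOVA false-positive rate", {
  d <- toy_design(9)
  cfg <- platform_sim_config("lcms", n_features = 400,
                             n_markers_per_attribute = 2, marker_effect = 0,
                             technical_cv = 0.2, n_tech_replicates = 4,
                             n_replicated_samples = 9, n_qc = 3,
                             n_background_features = 0, seed = 17)
  sim <- simulate_feature_table(d, toy_effect_map(), cfg)
  tab <- sim$table
  study <- tab$samples$sample_type == "study"
  x <- log(tab$intensities[study, , drop = FALSE])
  g <- factor(tab$samples$product_id[study])
  pvals <- apply(x, 2L, function(v) stats::anova(stats::lm(v ~ g))[1, 5])
  # at alpha = 0.01 about 1% of null features flag; allow 4 SE
  rate <- mean(pvals < 0.01)
  expect_lt(abs(rate - 0.01), 0.01 + 4 * sqrt(0.01 * 0.99 / 400))
})

test_that("strong markers track their attribute's true response", {
  d <- default_design()
  em <- default_effect_map()
  cfg <- platform_sim_config("lcms", n_features = 200,
                             n_markers_per_attribute = 2, marker_effect = 1.5,
                             technical_cv = 0.05, n_replicated_samples = 0,
                             n_qc = 3, n_background_features = 5, seed = 23)
  sim <- simulate_feature_table(d, em, cfg)
  mu <- true_response(d, em)
  tab <- sim$table
  study <- tab$samples$sample_type == "study"
  x <- log(tab$intensities[study, , drop = FALSE])
  prods <- tab$samples$product_id[study]
  mk <- sim$truth$marker_map[["garlic.fl"]]
  for (r in seq_len(nrow(mk))) {
    rr <- cor(x[, mk$feature_id[r]], mu[prods, "garlic.fl"])
    expect_gt(abs(rr), 0.9)
    expect_equal(sign(rr), sign(mk$effect[r]))
  }
})

test_that("study bundles are byte-identical under one master seed", {
  d <- toy_design(5)
  em <- toy_effect_map()
  args <- list(design = d, effects = em,
               panel_cfg = panel_sim_config(n_assessors = 3, n_sessions = 2),
               lcms_cfg = platform_sim_config("lcms", n_features = 30,
                                              n_markers_per_attribute = 2,
                                              n_qc = 3,
                                              n_background_features = 3),
               gcms_cfg = platform_sim_config("gcms", n_features = 25,
                                              n_markers_per_attribute = 2,
                                              n_qc = 3,
                                              n_background_features = 3),
               seed = 99)
  o1 <- withr::local_tempdir(); o2 <- withr::local_tempdir()
  do.call(simulate_study, c(list(out_dir = o1), args))
  do.call(simulate_study, c(list(out_dir = o2), args))
  for (f in list.files(o1)) {
    expect_identical(readLines(file.path(o1, f)),
                     readLines(file.path(o2, f)), label = f)
  }
})

test_that("half-coverage allocation still presents every product each session", {
  d <- default_design()
  cfg <- panel_sim_config(n_assessors = 14, n_sessions = 4,
                          design_coverage = 0.5, noise_sd = 0, seed = 8)
  sim <- simulate_panel(d, default_effect_map(), cfg)
  long <- attr(sim$scores, "long")
  per_session <- table(long$session, long$product_id) > 0
  expect_true(all(per_session))
  # and the tensor has missing cells (not every assessor saw every product)
  expect_gt(sum(is.na(sim$scores)), 0)
})
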