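# Standardization, pooled SD modes, back-transform, sensory responses,
# and the mixed-ANOVA product-effect F.

test_that("standardization matches the hand-computed two-product case", {
  ps <- panel_scores(toy_panel_long(matrix(c(40, 60), 1, 2)))
  out <- standardize_scores(ps)
  # mean 50, sample SD 14.142: z = (40-50)/14.142, (60-50)/14.142
  expect_equal(as.vector(out$z), c(-0.7071, 0.7071), tolerance = 1e-4)
  expect_equal(as.vector(out$stats$sd_ik), 14.1421, tolerance = 1e-4)
})

test_that("standardized slices have mean 0 and SD 1; idempotent", {
  sim <- simulate_panel(toy_design(8), toy_effect_map(),
                        panel_sim_config(n_assessors = 5, seed = 2))
  out <- standardize_scores(sim$scores)
  for (k in seq_len(dim(out$z)[3])) {
    for (i in seq_len(dim(out$z)[1])) {
      v <- out$z[i, , k]
      expect_lt(abs(mean(v)), 1e-10)
      expect_lt(abs(sd(v) - 1), 1e-10)
    }
  }
  again <- standardize_scores(out$z)
  expect_equal(again$z, out$z, tolerance = 1e-10)
})

test_that("constant assessor slices are dropped with an informative warning", {
  m <- matrix(c(50, 50, 40, 60), 2, 2, byrow = TRUE)
  ps <- panel_scores(toy_panel_long(m))
  expect_warning(out <- standardize_scores(ps), "A01.*umami.fl")
  expect_true(all(is.na(out$z[1, , 1])))
  expect_false(anyNA(out$z[2, , 1]))
  expect_error(standardize_scores(ps, on_constant = "error"), "constant")
})

test_that("pooled SD: conventional and literal modes follow their formulas", {
  stats_obj <- structure(list(
    mean_ik = matrix(c(50, 50), 2, 1, dimnames = list(NULL, "a")),
    sd_ik = matrix(c(2, 4), 2, 1, dimnames = list(NULL, "a")),
    mean_k = c(a = 50), pooled = NULL, pooled_mode = NULL),
    class = "standardization_stats")
  conv <- pooled_sd(stats_obj, n_products = 3)
  expect_equal(unname(conv$pooled), sqrt((4 + 16) / 2), tolerance = 1e-10)
  expect_equal(unname(conv$pooled), 3.1623, tolerance = 1e-4)
  lit <- pooled_sd(stats_obj, n_products = 3, mode = "literal")
  expect_equal(unname(lit$pooled), (2 + 4) / (2 * 2), tolerance = 1e-10)
  expect_equal(unname(lit$pooled), 1.5)
  # equal per-assessor SDs: conventional pooled SD is that value
  stats_obj$sd_ik[] <- c(3, 3)
  expect_equal(unname(pooled_sd(stats_obj, 3)$pooled), 3, tolerance = 1e-12)
})

test_that("back-transform restores attribute means and pooled spread", {
  sim <- simulate_panel(toy_design(10), toy_effect_map(),
                        panel_sim_config(n_assessors = 6, seed = 4))
  out <- standardize_scores(sim$scores)
  st <- pooled_sd(out$stats, n_products = 10)
  ys <- back_transform(out$z, st)
  y <- unclass(sim$scores)
  for (k in seq_len(dim(ys)[3])) {
    expect_equal(mean(ys[, , k]), mean(y[, , k]), tolerance = 1e-10)
    # each assessor slice of z has SD 1, so each back-transformed slice has
    # SD sp_k exactly
    expect_equal(unname(sd(ys[1, , k])), unname(st$pooled[k]),
                 tolerance = 1e-10)
  }
  # zero standardized scores map to the attribute mean
  z0 <- out$z; z0[] <- 0
  y0 <- back_transform(z0, st)
  for (k in seq_len(dim(ys)[3])) {
    expect_equal(unique(as.vector(y0[, , k])), unname(st$mean_k[k]))
  }
  # monotone affine map: within-assessor product ranking preserved
  for (i in seq_len(dim(ys)[1])) {
    expect_equal(order(ys[i, , 1]), order(y[i, , 1]))
  }
})

test_that("sensory responses average assessors and recover mu when noiseless", {
  arr <- array(c(30, 50, 20, 40), dim = c(2, 1, 2),
               dimnames = list(c("A1", "A2"), "P1", c("k1", "k2")))
  nu <- sensory_response(arr)
  expect_equal(as.vector(nu), c(40, 30))

  d <- toy_design(8)
  # only driven attributes: a flat attribute is constant in the noiseless
  # limit and its slices are dropped by design
  em <- effect_map(data.frame(attribute = c("tomato.fl", "garlic.fl"),
                              factor = c("tomato_dose", "yeast_product"),
                              level = c("high", "G28"),
                              effect = c(15, 20)),
                   baselines = c(tomato.fl = 40, garlic.fl = 30))
  sim <- simulate_panel(d, em, panel_sim_config(
    n_assessors = 4, assessor_offset_sd = 8, assessor_scale_sd = 0.2,
    noise_sd = 0, seed = 6))
  out <- standardize_scores(sim$scores)
  ys <- back_transform(out$z, pooled_sd(out$stats, 8))
  nu <- sensory_response(ys)
  mu <- true_response(d, em)
  for (k in colnames(mu)) {
    if (sd(mu[, k]) == 0) next
    expect_equal(cor(nu[, k], mu[rownames(nu), k], method = "spearman"), 1)
  }
})

test_that("mixed-ANOVA F matches the two-way ANOVA oracle on balanced data", {
  set.seed(31)
  I <- 6; J <- 8
  y <- outer(rnorm(I, 0, 5), rnorm(J, 50, 8), `+`) + rnorm(I * J, 0, 3)
  y <- pmin(pmax(y, 0), 100)
  arr <- array(y, dim = c(I, J, 1),
               dimnames = list(sprintf("A%d", 1:I), sprintf("P%d", 1:J), "x"))
  res <- product_f_values(arr)
  # independent closed-form oracle: two-way ANOVA, product + assessor blocks
  df <- data.frame(score = as.vector(y),
                   assessor = factor(rep(1:I, J)),
                   product = factor(rep(1:J, each = I)))
  an <- anova(lm(score ~ assessor + product, df))
  f_oracle <- an["product", "Mean Sq"] / an["Residuals", "Mean Sq"]
  expect_equal(res$F, f_oracle, tolerance = 1e-6)
  expect_equal(res$df_num, J - 1)
  expect_equal(res$df_den, (I - 1) * (J - 1), tolerance = 1e-6)
  expect_equal(res$critical_F, qf(0.95, J - 1, (I - 1) * (J - 1)),
               tolerance = 1e-6)
})

test_that("F is invariant to per-assessor affine transforms after standardization", {
  sim <- simulate_panel(toy_design(8), toy_effect_map(),
                        panel_sim_config(n_assessors = 5, noise_sd = 4,
                                         seed = 12))
  y <- unclass(sim$scores)[, , "tomato.fl", drop = FALSE]
  y2 <- y
  for (i in seq_len(dim(y)[1])) y2[i, , ] <- 0.5 * y[i, , ] + 10 * i / 7
  z1 <- standardize_scores(y)$z
  z2 <- standardize_scores(y2)$z
  f1 <- product_f_values(z1)$F
  f2 <- product_f_values(z2)$F
  expect_equal(f1, f2, tolerance = 1e-8)
})

test_that("F grows with the simulated product-effect size", {
  d <- toy_design(9)
  meds <- sapply(c(0, 6, 14), function(eff) {
    em <- effect_map(data.frame(attribute = "umami.fl",
                                factor = "tomato_dose", level = "high",
                                effect = eff),
                     baselines = c(umami.fl = 45))
    f <- sapply(1:4, function(s) {
      sim <- simulate_panel(d, em, panel_sim_config(
        n_assessors = 6, noise_sd = 5, seed = 100 + s))
      product_f_values(unclass(sim$scores))$F
    })
    median(f)
  })
  expect_true(all(diff(meds) > 0))
})

test_that("strong-effect attribute outranks pure noise in F nearly always", {
  d <- toy_design(9)
  em <- effect_map(data.frame(attribute = "tomato.fl",
                              factor = "tomato_dose", level = "high",
                              effect = 15),
                   baselines = c(tomato.fl = 40, drying.af = 45))
  wins <- sapply(1:10, function(s) {
    sim <- simulate_panel(d, em, panel_sim_config(n_assessors = 6,
                                                  noise_sd = 5,
                                                  seed = 200 + s))
    f <- product_f_values(unclass(sim$scores))
    f$F[f$attribute == "tomato.fl"] > f$F[f$attribute == "drying.af"]
  })
  expect_gte(mean(wins), 0.95)
})
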