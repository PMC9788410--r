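# Synthetic study generator: coupled panel scores and dual-platform feature
# tables with known ground truth (marker map, assessor biases, true product
# effects) for recovery benchmarking.

#' Construct an effect map
#'
#' An effect map encodes the "true" product effects the panel observes: per
#' attribute a baseline score plus additive shifts tied to design factor
#' levels. The per-product true response is
#' `mu[j, k] = baseline[k] + sum of effects whose (factor, level) matches
#' product j`.
#'
#' @param effects data.frame with columns `attribute`, `factor`, `level`,
#'   `effect` (score units).
#' @param baselines named numeric vector of per-attribute baselines (score
#'   units); attributes in `effects` missing here default to 50.
#' @return an `effect_map` object.
#' @export
effect_map <- function(effects, baselines = NULL) {
  effects <- as.data.frame(effects, stringsAsFactors = FALSE)
  need <- c("attribute", "factor", "level", "effect")
  if (length(setdiff(need, names(effects)))) {
    stopf("effect map needs columns: %s", paste(need, collapse = ", "))
  }
  effects$effect <- as.numeric(effects$effect)
  attrs <- unique(effects$attribute)
  if (is.null(baselines)) baselines <- numeric(0)
  miss <- setdiff(attrs, names(baselines))
  baselines <- c(baselines, stats::setNames(rep(50, length(miss)), miss))
  structure(list(effects = effects, baselines = baselines),
            class = "effect_map")
}

#' True product x attribute response matrix implied by an effect map
#'
#' @param design a `study_design`.
#' @param effects an `effect_map`.
#' @return numeric matrix `[product, attribute]` of true responses (mu).
#' @export
true_response <- function(design, effects) {
  stopifnot(inherits(design, "study_design"), inherits(effects, "effect_map"))
  ef <- effects$effects
  bad_fac <- setdiff(ef$factor, setdiff(.design_cols, "product_id"))
  if (length(bad_fac)) stopf("effect map references unknown factor '%s'",
                             bad_fac[1L])
  for (r in seq_len(nrow(ef))) {
    if (!ef$level[r] %in% design[[ef$factor[r]]]) {
      stopf("effect map level '%s' not observed for factor '%s'",
            ef$level[r], ef$factor[r])
    }
  }
  attrs <- names(effects$baselines)
  mu <- matrix(rep(effects$baselines, each = nrow(design)),
               nrow = nrow(design),
               dimnames = list(design$product_id, attrs))
  for (r in seq_len(nrow(ef))) {
    hit <- design[[ef$factor[r]]] == ef$level[r]
    mu[hit, ef$attribute[r]] <- mu[hit, ef$attribute[r]] + ef$effect[r]
  }
  mu
}

#' Default graded effect map over the 26 default attributes
#'
#' Tomato attributes are driven by tomato dosage, garlic/onion attributes by
#' the G28/O31 yeast codes, umami and yeast notes by yeast dosage, with
#' graded magnitudes down to several null attributes — so that the
#' attribute-level spread of product-effect F values and downstream Q2
#' mirrors a real panel's mix of discriminating and flat attributes.
#'
#' @return an `effect_map` over [default_attributes()].
#' @export
default_effect_map <- function() {
  e <- rbind(
    data.frame(attribute = "tomato.od",     factor = "tomato_dose",   level = "high", effect = 16),
    data.frame(attribute = "tomato.fl",     factor = "tomato_dose",   level = "high", effect = 14),
    data.frame(attribute = "sweet.fl",      factor = "tomato_dose",   level = "high", effect = 10),
    data.frame(attribute = "intensity.od",  factor = "tomato_dose",   level = "high", effect = 9),
    data.frame(attribute = "intensity.od",  factor = "yeast_dose",    level = "high", effect = 6),
    data.frame(attribute = "intensity.fl",  factor = "tomato_dose",   level = "high", effect = 8),
    data.frame(attribute = "intensity.fl",  factor = "yeast_dose",    level = "high", effect = 7),
    data.frame(attribute = "garlic.fl",     factor = "yeast_product", level = "G28",  effect = 22),
    data.frame(attribute = "garlic.od",     factor = "yeast_product", level = "G28",  effect = 17),
    data.frame(attribute = "onion.fl",      factor = "yeast_product", level = "O31",  effect = 18),
    data.frame(attribute = "onion.od",      factor = "yeast_product", level = "O31",  effect = 13),
    data.frame(attribute = "umami.fl",      factor = "yeast_dose",    level = "high", effect = 11),
    data.frame(attribute = "umami.fl",      factor = "yeast_product", level = "YPr",  effect = 6),
    data.frame(attribute = "umami.at",      factor = "yeast_dose",    level = "high", effect = 8),
    data.frame(attribute = "yeast.od",      factor = "yeast_dose",    level = "high", effect = 10),
    data.frame(attribute = "yeast.fl",      factor = "yeast_dose",    level = "high", effect = 9),
    data.frame(attribute = "yeast.fl",      factor = "yeast_dose",    level = "low",  effect = 4),
    data.frame(attribute = "bitter.fl",     factor = "yeast_product", level = "G28",  effect = 7),
    data.frame(attribute = "bitter.fl",     factor = "heat",          level = "long", effect = 4),
    data.frame(attribute = "bitter.at",     factor = "heat",          level = "long", effect = 5),
    data.frame(attribute = "salty.fl",      factor = "yeast_dose",    level = "high", effect = 6),
    data.frame(attribute = "salty.at",      factor = "yeast_dose",    level = "high", effect = 4),
    data.frame(attribute = "sour.fl",       factor = "tomato_dose",   level = "high", effect = 5),
    data.frame(attribute = "sour.od",       factor = "tomato_dose",   level = "high", effect = 3),
    data.frame(attribute = "thickness.mf",  factor = "tomato_dose",   level = "high", effect = 8),
    data.frame(attribute = "watery.mf",     factor = "tomato_dose",   level = "low",  effect = 9),
    data.frame(attribute = "mouthfullness.mf", factor = "yeast_dose", level = "high", effect = 5),
    data.frame(attribute = "creamy.mf",     factor = "oil_type",      level = "olive", effect = 3),
    data.frame(attribute = "intensity.at",  factor = "yeast_dose",    level = "high", effect = 5),
    data.frame(attribute = "coating.af",    factor = "oil_type",      level = "olive", effect = 2)
    # drying.af left null: a flat attribute the panel cannot discriminate on
  )
  baselines <- stats::setNames(rep(40, length(default_attributes())),
                               default_attributes())
  effect_map(e, baselines)
}

#' Panel simulation configuration
#'
#' @param n_assessors number of trained assessors (default 14).
#' @param n_sessions number of tasting sessions (default 4); all products
#'   appear in each session.
#' @param assessor_offset_sd SD of per-assessor additive offsets, score units.
#' @param assessor_scale_sd SD of per-assessor log multiplicative gain.
#' @param noise_sd residual scoring noise SD, score units.
#' @param design_coverage fraction of (assessor, product) cells assessed per
#'   session; below 1 a cyclic balanced-incomplete allocation is used.
#' @param seed integer RNG seed.
#' @return a `panel_sim_config` list.
#' @export
panel_sim_config <- function(n_assessors = 14, n_sessions = 4,
                             assessor_offset_sd = 6, assessor_scale_sd = 0.12,
                             noise_sd = 6, design_coverage = 1.0, seed = 1L) {
  stopifnot(n_assessors >= 2, n_sessions >= 1,
            design_coverage > 0, design_coverage <= 1)
  structure(list(n_assessors = as.integer(n_assessors),
                 n_sessions = as.integer(n_sessions),
                 assessor_offset_sd = assessor_offset_sd,
                 assessor_scale_sd = assessor_scale_sd,
                 noise_sd = noise_sd,
                 design_coverage = design_coverage,
                 seed = as.integer(seed)),
            class = "panel_sim_config")
}

# cyclic balanced-incomplete allocation: assessor i starts its product window
# at an evenly staggered position, rotated by one each session, so every
# product appears in every session as long as I * m >= J.
allocate_products <- function(n_products, n_assessors, coverage, session) {
  m <- max(1L, ceiling(coverage * n_products))
  if (m >= n_products) {
    return(replicate(n_assessors, seq_len(n_products), simplify = FALSE))
  }
  starts <- floor((seq_len(n_assessors) - 1L) * n_products / n_assessors)
  lapply(starts, function(s0) {
    ((s0 + session - 1L + seq_len(m) - 1L) %% n_products) + 1L
  })
}

#' Simulate trained-panel QDA scores
#'
#' Scoring model per cell: `y = clip(a_i + b_i * mu[j, k] + eps, 0, 100)`
#' with assessor offset `a_i ~ N(0, assessor_offset_sd^2)`, gain
#' `log b_i ~ N(0, assessor_scale_sd^2)` and noise
#' `eps ~ N(0, noise_sd^2)` drawn independently per session.
#'
#' @param design a `study_design`.
#' @param effects an `effect_map`.
#' @param cfg a [panel_sim_config()].
#' @return list with `scores` (a [panel_scores()] tensor) and `truth` (list
#'   with `mu`, per-assessor `offset` and `scale`, and the clipping
#'   fraction).
#' @export
simulate_panel <- function(design, effects, cfg = panel_sim_config()) {
  stopifnot(inherits(design, "study_design"), inherits(effects, "effect_map"),
            inherits(cfg, "panel_sim_config"))
  mu <- true_response(design, effects)
  J <- nrow(mu); K <- ncol(mu); I <- cfg$n_assessors
  with_seed(cfg$seed, {
    a <- stats::rnorm(I, 0, cfg$assessor_offset_sd)
    b <- exp(stats::rnorm(I, 0, cfg$assessor_scale_sd))
    rows <- vector("list", cfg$n_sessions * I)
    n_clipped <- 0L; n_total <- 0L
    for (s in seq_len(cfg$n_sessions)) {
      alloc <- allocate_products(J, I, cfg$design_coverage, s)
      for (i in seq_len(I)) {
        js <- alloc[[i]]
        raw <- a[i] + b[i] * mu[js, , drop = FALSE] +
          matrix(stats::rnorm(length(js) * K, 0, cfg$noise_sd),
                 nrow = length(js))
        n_clipped <- n_clipped + sum(raw < 0 | raw > 100)
        n_total <- n_total + length(raw)
        y <- pmin(pmax(raw, 0), 100)
        rows[[(s - 1L) * I + i]] <- data.frame(
          assessor_id = sprintf("A%02d", i),
          session = s,
          product_id = rep(rownames(mu)[js], times = K),
          attribute = rep(colnames(mu), each = length(js)),
          score = as.vector(y),
          stringsAsFactors = FALSE)
      }
    }
    long <- do.call(rbind, rows)
    truth <- list(mu = mu,
                  offset = stats::setNames(a, sprintf("A%02d", seq_len(I))),
                  scale = stats::setNames(b, sprintf("A%02d", seq_len(I))),
                  clip_fraction = n_clipped / n_total)
    list(scores = panel_scores(long), truth = truth)
  })
}

#' Platform simulation configuration
#'
#' @param platform "lcms" or "gcms".
#' @param n_features number of abstract feature columns.
#' @param n_markers_per_attribute marker features planted per attribute.
#' @param marker_effect log-intensity shift per unit of the attribute's
#'   standardized design contrast.
#' @param baseline_log_mean,baseline_log_sd distribution of per-feature
#'   baseline log intensities.
#' @param technical_cv technical coefficient of variation (fraction); the
#'   log-scale noise SD is `sqrt(log(1 + cv^2))`.
#' @param n_tech_replicates replicate injections for the replicated subset.
#' @param n_replicated_samples how many products get technical replicates
#'   (default 12, the quadruplicate subset).
#' @param n_qc pooled QC injections, interleaved every `qc_spacing` study
#'   injections.
#' @param n_blank blank injections (background-only intensities).
#' @param qc_spacing study injections between consecutive QCs.
#' @param n_background_features features dominated by blank background (as
#'   abundant in blanks as in study samples); targets of the blank filter.
#' @param correlated_block_size if > 1, consecutive non-marker features are
#'   grouped into blocks sharing a per-product latent factor (adduct/isotope
#'   analogue) with pairwise log-scale correlation >= 0.9 at small
#'   technical noise.
#' @param seed integer RNG seed.
#' @return a `platform_sim_config` list.
#' @export
platform_sim_config <- function(platform = c("lcms", "gcms"),
                                n_features = 500,
                                n_markers_per_attribute = 5,
                                marker_effect = 1.0,
                                baseline_log_mean = 10, baseline_log_sd = 1,
                                technical_cv = 0.05,
                                n_tech_replicates = 4,
                                n_replicated_samples = 12,
                                n_qc = 8, n_blank = 3, qc_spacing = 10,
                                n_background_features = 20,
                                correlated_block_size = 1,
                                seed = 1L) {
  platform <- match.arg(platform)
  stopifnot(n_features >= 1, technical_cv >= 0, n_tech_replicates >= 1,
            correlated_block_size >= 1)
  structure(list(platform = platform, n_features = as.integer(n_features),
                 n_markers_per_attribute = as.integer(n_markers_per_attribute),
                 marker_effect = marker_effect,
                 baseline_log_mean = baseline_log_mean,
                 baseline_log_sd = baseline_log_sd,
                 technical_cv = technical_cv,
                 n_tech_replicates = as.integer(n_tech_replicates),
                 n_replicated_samples = as.integer(n_replicated_samples),
                 n_qc = as.integer(n_qc), n_blank = as.integer(n_blank),
                 qc_spacing = as.integer(qc_spacing),
                 n_background_features = as.integer(n_background_features),
                 correlated_block_size = as.integer(correlated_block_size),
                 seed = as.integer(seed)),
            class = "platform_sim_config")
}

#' Simulate a post-peak-picking feature table
#'
#' Marker feature f planted for attribute k follows
#' `log x = baseline_f + beta_f * c_j + tech noise`, where `c_j` is the
#' attribute's true response standardized to unit SD across products and
#' `|beta_f| = marker_effect` with alternating signs. Non-markers carry
#' baseline + noise (optionally a shared per-product latent factor within
#' correlated blocks); background features are equally abundant in blank and
#' study samples; QC rows are the pooled study mean plus technical noise.
#'
#' @param design a `study_design`.
#' @param effects an `effect_map`.
#' @param cfg a [platform_sim_config()].
#' @return list with `table` (a [feature_table()]) and `truth` (marker map,
#'   background feature ids, correlated blocks, true contrasts).
#' @export
simulate_feature_table <- function(design, effects,
                                   cfg = platform_sim_config()) {
  stopifnot(inherits(design, "study_design"), inherits(effects, "effect_map"),
            inherits(cfg, "platform_sim_config"))
  mu <- true_response(design, effects)
  J <- nrow(mu)
  attrs <- colnames(mu)
  n_marker_total <- cfg$n_markers_per_attribute * length(attrs)
  if (n_marker_total + cfg$n_background_features > cfg$n_features) {
    stopf("marker budget (%d markers + %d background) exceeds n_features = %d",
          n_marker_total, cfg$n_background_features, cfg$n_features)
  }
  # standardized per-attribute design contrast (zero vector if attribute flat)
  contrasts <- apply(mu, 2, function(v) {
    s <- sd_sample(v)
    if (is.na(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
  })
  rownames(contrasts) <- rownames(mu)

  log_sd_tech <- if (cfg$technical_cv > 0) sqrt(log(1 + cfg$technical_cv^2)) else 0

  with_seed(cfg$seed, {
    feat_ids <- sprintf("%s_F%04d", toupper(cfg$platform),
                        seq_len(cfg$n_features))
    baseline <- stats::rnorm(cfg$n_features, cfg$baseline_log_mean,
                             cfg$baseline_log_sd)
    # assign roles: markers first, then background, remainder plain noise
    marker_idx <- seq_len(n_marker_total)
    background_idx <- n_marker_total + seq_len(cfg$n_background_features)
    marker_map <- list()
    beta <- numeric(cfg$n_features)
    marker_attr <- rep(NA_character_, cfg$n_features)
    for (ai in seq_along(attrs)) {
      idx <- marker_idx[(ai - 1L) * cfg$n_markers_per_attribute +
                          seq_len(cfg$n_markers_per_attribute)]
      sgn <- rep_len(c(1, -1), length(idx))
      beta[idx] <- cfg$marker_effect * sgn
      marker_attr[idx] <- attrs[ai]
      marker_map[[attrs[ai]]] <- data.frame(feature_id = feat_ids[idx],
                                            effect = beta[idx],
                                            stringsAsFactors = FALSE)
    }
    # correlated blocks over the plain-noise remainder
    noise_idx <- setdiff(seq_len(cfg$n_features),
                         c(marker_idx, background_idx))
    block_id <- rep(NA_integer_, cfg$n_features)
    if (cfg$correlated_block_size > 1L && length(noise_idx) > 1L) {
      block_id[noise_idx] <-
        rep(seq_along(noise_idx), each = cfg$correlated_block_size,
            length.out = length(noise_idx))
    }
    n_blocks <- if (all(is.na(block_id))) 0L else max(block_id, na.rm = TRUE)
    block_latent <- if (n_blocks > 0L) {
      matrix(stats::rnorm(J * n_blocks), nrow = J)  # per-product latent
    } else NULL

    # per-product expected log intensity for study samples
    expected_log <- matrix(rep(baseline, each = J), nrow = J,
                           dimnames = list(rownames(mu), feat_ids))
    for (f in which(beta != 0)) {
      expected_log[, f] <- expected_log[, f] +
        beta[f] * contrasts[, marker_attr[f]]
    }
    if (n_blocks > 0L) {
      for (f in which(!is.na(block_id))) {
        expected_log[, f] <- expected_log[, f] + block_latent[, block_id[f]]
      }
    }

    # sample manifest: replicated subset first (deterministic choice: the
    # first n_replicated_samples products in design order)
    n_rep <- min(cfg$n_replicated_samples, J)
    reps <- rep(1L, J)
    if (n_rep > 0L) reps[seq_len(n_rep)] <- cfg$n_tech_replicates
    study <- data.frame(product_id = rep(rownames(mu), times = reps),
                        replicate_id = unlist(lapply(reps, seq_len)),
                        stringsAsFactors = FALSE)
    study <- study[sample.int(nrow(study)), , drop = FALSE]  # run order

    # interleave QCs every qc_spacing study injections; blanks lead the run
    seq_rows <- list()
    for (b in seq_len(cfg$n_blank)) {
      seq_rows[[length(seq_rows) + 1L]] <-
        data.frame(product_id = NA_character_, sample_type = "blank",
                   replicate_id = b, stringsAsFactors = FALSE)
    }
    qc_left <- cfg$n_qc
    qc_n <- 0L
    for (r in seq_len(nrow(study))) {
      if (qc_left > 0L && (r - 1L) %% cfg$qc_spacing == 0L) {
        qc_n <- qc_n + 1L; qc_left <- qc_left - 1L
        seq_rows[[length(seq_rows) + 1L]] <-
          data.frame(product_id = NA_character_, sample_type = "qc",
                     replicate_id = qc_n, stringsAsFactors = FALSE)
      }
      seq_rows[[length(seq_rows) + 1L]] <-
        data.frame(product_id = study$product_id[r], sample_type = "study",
                   replicate_id = study$replicate_id[r],
                   stringsAsFactors = FALSE)
    }
    while (qc_left > 0L) {
      qc_n <- qc_n + 1L; qc_left <- qc_left - 1L
      seq_rows[[length(seq_rows) + 1L]] <-
        data.frame(product_id = NA_character_, sample_type = "qc",
                   replicate_id = qc_n, stringsAsFactors = FALSE)
    }
    manifest <- do.call(rbind, seq_rows)
    manifest$injection_order <- seq_len(nrow(manifest))
    manifest$batch <- 1L
    manifest$sample_id <- sprintf("%s_S%03d", toupper(cfg$platform),
                                  manifest$injection_order)

    pooled_log <- colMeans(expected_log)  # QC = pooled study mean
    # blanks: background features at study-level abundance, everything else
    # at trace level far below it
    blank_log <- baseline - 9
    blank_log[background_idx] <- baseline[background_idx]

    logx <- matrix(NA_real_, nrow(manifest), cfg$n_features,
                   dimnames = list(manifest$sample_id, feat_ids))
    for (r in seq_len(nrow(manifest))) {
      base_r <- switch(manifest$sample_type[r],
                       study = expected_log[manifest$product_id[r], ],
                       qc = pooled_log,
                       blank = blank_log)
      logx[r, ] <- base_r
    }
    if (log_sd_tech > 0) {
      logx <- logx + matrix(stats::rnorm(length(logx), 0, log_sd_tech),
                            nrow = nrow(logx))
    }
    tab <- feature_table(exp(logx),
                         manifest[, c("sample_id", "product_id", "sample_type",
                                      "replicate_id", "batch",
                                      "injection_order")],
                         platform = cfg$platform, design = design)
    truth <- list(marker_map = marker_map,
                  background_features = feat_ids[background_idx],
                  blocks = split(feat_ids[!is.na(block_id)],
                                 block_id[!is.na(block_id)]),
                  contrasts = contrasts,
                  beta = stats::setNames(beta, feat_ids))
    list(table = tab, truth = truth)
  })
}

#' Simulate and write a complete study bundle
#'
#' Generates a coupled panel + LC-MS + GC-MS dataset from one master seed
#' (child seeds are derived deterministically in the order panel, LC-MS,
#' GC-MS) and writes every artifact in the package's CSV/JSON schemas.
#'
#' @param out_dir output directory (created if absent).
#' @param design a `study_design` (default [default_design()]).
#' @param effects an `effect_map` (default [default_effect_map()]).
#' @param panel_cfg a [panel_sim_config()]; its seed is overridden.
#' @param lcms_cfg,gcms_cfg [platform_sim_config()]s; seeds overridden.
#' @param seed master seed.
#' @return invisibly, a list with the in-memory `design`, `panel`, `lcms`,
#'   `gcms` objects, their ground truths, and the file `paths`.
#' @export
simulate_study <- function(out_dir, design = default_design(),
                           effects = default_effect_map(),
                           panel_cfg = panel_sim_config(),
                           lcms_cfg = platform_sim_config("lcms"),
                           gcms_cfg = platform_sim_config("gcms",
                                                          n_features = 300),
                           seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(seed, 3L)
  panel_cfg$seed <- seeds[1L]
  lcms_cfg$seed <- seeds[2L]
  gcms_cfg$seed <- seeds[3L]
  panel <- simulate_panel(design, effects, panel_cfg)
  lcms <- simulate_feature_table(design, effects, lcms_cfg)
  gcms <- simulate_feature_table(design, effects, gcms_cfg)

  paths <- list(design = file.path(out_dir, "design.csv"),
                panel = file.path(out_dir, "panel_scores.csv"),
                features_lcms = file.path(out_dir, "features_lcms.csv"),
                samples_lcms = file.path(out_dir, "samples_lcms.csv"),
                features_gcms = file.path(out_dir, "features_gcms.csv"),
                samples_gcms = file.path(out_dir, "samples_gcms.csv"),
                ground_truth = file.path(out_dir, "ground_truth.json"),
                manifest = file.path(out_dir, "manifest.json"))
  write_design(design, paths$design)
  write_panel_scores(panel$scores, paths$panel)
  write_feature_table(lcms$table, paths$features_lcms, paths$samples_lcms)
  write_feature_table(gcms$table, paths$features_gcms, paths$samples_gcms)
  truth <- list(panel = list(mu = panel$truth$mu,
                             offset = panel$truth$offset,
                             scale = panel$truth$scale,
                             clip_fraction = panel$truth$clip_fraction),
                lcms = lcms$truth[c("marker_map", "background_features",
                                    "blocks", "beta")],
                gcms = gcms$truth[c("marker_map", "background_features",
                                    "blocks", "beta")])
  jsonlite::write_json(truth, paths$ground_truth, digits = NA, pretty = TRUE)
  jsonlite::write_json(list(master_seed = seed,
                            child_seeds = list(panel = seeds[1L],
                                               lcms = seeds[2L],
                                               gcms = seeds[3L]),
                            panel_cfg = unclass(panel_cfg),
                            lcms_cfg = unclass(lcms_cfg),
                            gcms_cfg = unclass(gcms_cfg)),
                       paths$manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(list(design = design, panel = panel, lcms = lcms, gcms = gcms,
                 paths = paths))
}
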