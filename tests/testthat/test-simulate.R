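small_cfg <- function(...) {
  sim_config(
    n_genes = 60, n_pairs_per_subtype = 4,
    n_planted_hyper = 4, n_planted_hypo = 4, n_shared = 2,
    n_integrated_hyper = 2, n_integrated_hypo = 2,
    n_clinical = 40, ...
  )
}

test_that("identical seed and config reproduce the cohort bitwise", {
  a <- simulate_cohort(small_cfg(seed = 7))
  b <- simulate_cohort(small_cfg(seed = 7))
  expect_identical(a$counts, b$counts)
  expect_identical(a$expression, b$expression)
  expect_identical(a$clinical, b$clinical)
  expect_identical(a$truth$planted, b$truth$planted)
  c <- simulate_cohort(small_cfg(seed = 8))
  expect_false(identical(a$counts, c$counts))
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(123)
  x1 <- runif(3)
  set.seed(123)
  invisible(simulate_cohort(small_cfg()))
  x2 <- runif(3)
  expect_identical(x1, x2)
})

test_that("planted truth bookkeeping matches the requested counts exactly", {
  cfg <- small_cfg()
  co <- simulate_cohort(cfg)
  tr <- co$truth
  for (s in cfg$subtypes) {
    expect_length(tr$specific_hyper[[s]], cfg$n_planted_hyper)
    expect_length(tr$specific_hypo[[s]], cfg$n_planted_hypo)
  }
  expect_length(tr$shared, cfg$n_shared)
  all_planted <- unname(c(
    unlist(tr$specific_hyper), unlist(tr$specific_hypo), tr$shared
  ))
  expect_false(anyDuplicated(all_planted) > 0) # disjoint by construction
  expect_equal(sort(unique(tr$planted$gene_id)), sort(all_planted))
})

test_that("config invariants are enforced with messages naming the bound", {
  expect_error(sim_config(effect_size = 1), "effect_size")
  expect_error(sim_config(hazard_ratio = 0), "hazard_ratio")
  expect_error(sim_config(censoring_rate = 1), "censoring_rate")
  expect_error(
    sim_config(n_genes = 10, n_planted_hyper = 5, n_planted_hypo = 5),
    "n_genes"
  )
  # the null configuration is legal
  expect_s3_class(sim_config(effect_size = 0, hazard_ratio = 1), "sim_config")
})

test_that("planted latent tumor-normal difference matches the configured effect", {
  # single-subtype cohort; estimate the latent fraction from unscaled ams
  cfg <- sim_config(
    n_genes = 500, n_pairs_per_subtype = 10, subtypes = "TNBC",
    n_planted_hyper = 0, n_planted_hypo = 20, n_shared = 0,
    n_integrated_hyper = 0, n_integrated_hypo = 0,
    effect_size = 0.3, seed = 11
  )
  co <- simulate_cohort(cfg)
  key <- match(co$counts[[1]], co$rois$feature_id)
  ams <- compute_ams(
    co$counts, co$rois$length[key], co$library_sizes, co$rois$cpg_count[key]
  )
  frac_hat <- as.matrix(ams[, -1]) / cfg$depth_factor
  rownames(frac_hat) <- ams[[1]]
  planted <- co$truth$planted
  feat <- paste(planted$gene_id, planted$target_region, sep = "|")
  idx <- match(feat, ams[[1]])
  tumor <- co$samples$sample[co$samples$tumor_normal == "tumor"]
  normal <- co$samples$sample[co$samples$tumor_normal == "normal"]
  diff <- rowMeans(frac_hat[idx, tumor, drop = FALSE]) -
    rowMeans(frac_hat[idx, normal, drop = FALSE])
  expect_lt(abs(mean(diff) - (-0.3)), 0.05)
})

test_that("null configuration leaves planted and null genes indistinguishable", {
  cfg <- small_cfg(effect_size = 0, hazard_ratio = 1, seed = 3)
  co <- simulate_cohort(cfg)
  key <- match(co$counts[[1]], co$rois$feature_id)
  sc <- minmax_scale(compute_ams(
    co$counts, co$rois$length[key], co$library_sizes, co$rois$cpg_count[key]
  ))
  calls <- call_dmrs(sc, co$samples, "TNBC")
  planted_feat <- paste(
    co$truth$planted$gene_id, co$truth$planted$target_region, sep = "|"
  )
  planted_p <- calls$p_value[calls$feature_id %in% planted_feat]
  null_p <- calls$p_value[!calls$feature_id %in% planted_feat]
  # same null distribution: a rank-sum test should not reject strongly
  expect_gt(wilcox.test(planted_p, null_p)$p.value, 0.01)
})

test_that("melting-curve boundaries and symmetry behave as a two-peak mixture", {
  # pure boundary mixtures: the off peak carries only Gaussian tail mass
  c0 <- simulate_melting_curve(0, noise_sd = 0)
  expect_lt(peak_auc(c0, c(82, 91)), 1e-3)
  expect_gt(peak_auc(c0, c(73, 82)), 0.9)
  expect_lt(hrm_metric(c0), 1e-3)
  c1 <- simulate_melting_curve(1, noise_sd = 0)
  expect_lt(peak_auc(c1, c(73, 82)), 1e-3)
  expect_gt(hrm_metric(c1), 1 - 1e-3)
  chalf <- simulate_melting_curve(0.5, noise_sd = 0)
  expect_equal(hrm_metric(chalf), 0.5, tolerance = 1e-6)
  expect_error(simulate_melting_curve(1.2), "true_fraction")
  expect_error(simulate_melting_curve(0.5, noise_sd = -1), "noise_sd")
})

test_that("simulate_survival honors censoring and group contracts", {
  d0 <- simulate_survival(rep(c("a", "b"), 20), 2, censoring_rate = 0)
  expect_true(all(d0$event == 1L))
  d <- simulate_survival(rep(c("a", "b"), 50), 1, censoring_rate = 0.3, seed = 5)
  expect_gt(mean(d$event == 0L), 0.1)
  expect_identical(
    simulate_survival(rep(c("a", "b"), 10), 2, seed = 9),
    simulate_survival(rep(c("a", "b"), 10), 2, seed = 9)
  )
  expect_error(simulate_survival(rep("a", 10), 2), "two distinct")
  expect_error(simulate_survival(rep(c("a", "b"), 5), -1), "hazard_ratio")
})

test_that("high-risk survival curve lies below the low-risk curve under HR = 3", {
  d <- simulate_survival(
    rep(c("high_risk", "low_risk"), each = 100), 3,
    seed = 21
  )
  km_hi <- km_estimate(d[d$group == "high_risk", ])
  km_lo <- km_estimate(d[d$group == "low_risk", ])
  t_med <- median(d$time)
  expect_lt(km_survival_at(km_hi, t_med), km_survival_at(km_lo, t_med))
})

test_that("log-rank on null simulated survival rejects near the nominal rate", {
  rejections <- vapply(1:40, function(s) {
    d <- simulate_survival(rep(c("a", "b"), 30), 1, seed = s)
    logrank_test(d)$p_value < 0.05
  }, logical(1L))
  expect_lt(mean(rejections), 0.2)
})
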