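test_that("expression differential is zero for identical groups and additive", {
  meta <- toy_samples(n_pairs = 3, subtypes = "TNBC")
  t_cols <- meta$sample[meta$tumor_normal == "tumor"]
  n_cols <- meta$sample[meta$tumor_normal == "normal"]
  base <- c(7.1, 8.3, 6.9)
  bal <- c(0.02, -0.02, 0) # mean-zero jitter keeps pair differences non-degenerate
  up <- c(0.9, 1.0, 1.1)
  expr <- tibble::tibble(gene_id = c("same", "up"))
  for (j in seq_along(n_cols)) {
    expr[[n_cols[j]]] <- c(base[j], base[j])
    expr[[t_cols[j]]] <- c(base[j] + bal[j], base[j] + up[j])
  }
  res <- expression_differential(expr, meta, "TNBC")
  expect_equal(res$log2_fold_change, c(0, 1), tolerance = 1e-12)

  # antisymmetry under swapping tumor/normal labels
  meta_sw <- dplyr::mutate(meta, tumor_normal = ifelse(
    tumor_normal == "tumor", "normal", "tumor"
  ))
  res_sw <- expression_differential(expr, meta_sw, "TNBC")
  expect_equal(res_sw$log2_fold_change, -res$log2_fold_change)
})

test_that("quadrant assignment applies the joint methylation-expression rule", {
  calls <- tibble::tibble(
    gene_id = c("a", "b", "c", "d"),
    call = c("hypo", "hyper", "hyper", "ns"),
    delta_mean = c(-0.3, 0.3, 0.25, 0.05)
  )
  expr <- tibble::tibble(
    gene_id = c("a", "b", "c", "d"),
    log2_fold_change = c(1.5, 0.1, -2, 3),
    p_value = c(0.001, 0.5, 0.001, 0.001),
    q_value = c(0.01, 0.6, 0.01, 0.01)
  )
  quad <- assign_quadrants(calls, expr, fc_threshold_log2 = log2(1.2))
  expect_equal(
    quad$quadrant[match(c("a", "b", "c", "d"), quad$gene_id)],
    c("hypo_up", "none", "hyper_down", "none")
  )
  expect_error(
    assign_quadrants(dplyr::bind_rows(calls, calls[1, ]), expr),
    "Duplicate"
  )
})

test_that("quadrant sizes partition the called-and-changed gene set", {
  set.seed(19)
  n <- 200
  calls <- tibble::tibble(
    gene_id = sprintf("g%03d", 1:n),
    call = sample(c("hypo", "hyper", "ns"), n, replace = TRUE),
    delta_mean = runif(n, -0.5, 0.5)
  )
  expr <- tibble::tibble(
    gene_id = calls$gene_id,
    log2_fold_change = rnorm(n),
    p_value = runif(n)^2,
    q_value = runif(n)
  )
  quad <- assign_quadrants(calls, expr)
  changed <- calls$call != "ns" &
    abs(expr$log2_fold_change) >= log2(1.2) & expr$p_value < 0.05
  expect_equal(sum(quad$quadrant != "none"), sum(changed))
})

test_that("gene-level collapse keeps the strongest called region", {
  calls <- tibble::tibble(
    feature_id = c("g|promoter", "g|CDS", "h|promoter", "h|CDS"),
    gene_id = c("g", "g", "h", "h"),
    region_class = c("promoter", "CDS", "promoter", "CDS"),
    delta_mean = c(-0.25, -0.35, 0.1, 0.05),
    p_value = c(0.01, 0.02, 0.2, 0.6),
    call = c("hypo", "hypo", "ns", "ns")
  )
  out <- collapse_gene_calls(calls)
  expect_equal(nrow(out), 2L)
  expect_equal(out$region_class[out$gene_id == "g"], "CDS")
  expect_equal(out$call[out$gene_id == "h"], "ns")
  expect_equal(out$p_value[out$gene_id == "h"], 0.2)
})

test_that("specificity sets follow exact set algebra", {
  s <- subtype_specific_sets(list(A = c("g1", "g2"), B = c("g2", "g3")))
  expect_equal(s$specific$A, "g1")
  expect_equal(s$specific$B, "g3")
  expect_equal(s$shared, "g2")

  same <- subtype_specific_sets(list(A = c("x", "y"), B = c("x", "y")))
  expect_equal(lengths(same$specific), c(A = 0L, B = 0L))
  expect_equal(sort(same$shared), c("x", "y"))

  disj <- subtype_specific_sets(list(A = "x", B = "y", C = "z"))
  expect_equal(disj$shared, character(0))
  expect_equal(unlist(disj$specific, use.names = FALSE), c("x", "y", "z"))

  td <- tidy(s)
  expect_equal(sort(td$gene_id), c("g1", "g2", "g3"))
  expect_error(subtype_specific_sets(list(A = "x")), "at least two")
})

test_that("specificity matches the membership-count oracle on random families", {
  set.seed(29)
  for (rep in 1:50) {
    k <- sample(2:5, 1)
    universe <- sprintf("g%02d", 1:30)
    sets <- setNames(
      lapply(seq_len(k), function(i) sample(universe, sample(0:20, 1))),
      paste0("S", seq_len(k))
    )
    got <- subtype_specific_sets(sets)
    want <- specificity_oracle(lapply(sets, unique))
    for (s in names(sets)) {
      expect_setequal(got$specific[[s]], want$specific[[s]])
    }
    expect_setequal(got$shared, want$shared)
    # pairwise disjointness of specific sets; shared disjoint from each
    all_spec <- unlist(got$specific, use.names = FALSE)
    expect_false(anyDuplicated(all_spec) > 0)
    expect_length(intersect(all_spec, got$shared), 0)
  }
})

test_that("candidate screen gates on margin sign and magnitude", {
  quad <- tibble::tibble(
    gene_id = c("good", "flat", "wrongsign"),
    quadrant = c("hypo_up", "hypo_up", "hypo_up")
  )
  subt <- c(a1 = "TNBC", a2 = "TNBC", b1 = "LumA", b2 = "LumA")
  mk <- function(vals) {
    m <- tibble::tibble(gene_id = quad$gene_id)
    for (j in seq_along(subt)) m[[names(subt)[j]]] <- vals[, j]
    m
  }
  meth <- mk(rbind(
    c(0.1, 0.2, 0.8, 0.9),  # good: TNBC hypomethylated
    c(0.5, 0.5, 0.5, 0.5),  # flat: zero margin
    c(0.9, 0.8, 0.1, 0.2)   # wrongsign: TNBC higher despite hypo call
  ))
  expr <- mk(rbind(
    c(9, 9.5, 6, 6.5),
    c(7, 7, 7, 7),
    c(9, 9.5, 6, 6.5)
  ))
  res <- candidate_screen(quad, meth, expr, subt, "TNBC")
  expect_true(res$passes[res$gene_id == "good"])
  expect_false(res$passes[res$gene_id == "flat"])
  expect_false(res$passes[res$gene_id == "wrongsign"])
  expect_equal(res$gene_id[1], "good")
  expect_equal(res$score[res$gene_id == "flat"], 0)

  # absent gene skipped with a warning
  quad2 <- dplyr::bind_rows(quad, tibble::tibble(gene_id = "ghost", quadrant = "hypo_up"))
  expect_warning(res2 <- candidate_screen(quad2, meth, expr, subt, "TNBC"), "ghost")
  expect_false("ghost" %in% res2$gene_id)
})

test_that("planted subtype-specific integrated genes are recovered end to end", {
  cfg <- sim_config(
    n_genes = 200, n_pairs_per_subtype = 6,
    n_planted_hyper = 6, n_planted_hypo = 6, n_shared = 2,
    n_integrated_hyper = 4, n_integrated_hypo = 4,
    n_clinical = 60, seed = 77
  )
  co <- simulate_cohort(cfg)
  key <- match(co$counts[[1]], co$rois$feature_id)
  sc <- minmax_scale(compute_ams(
    co$counts, co$rois$length[key], co$library_sizes, co$rois$cpg_count[key]
  ))
  call_sets <- lapply(
    setNames(cfg$subtypes, cfg$subtypes),
    function(s) {
      cc <- call_dmrs(sc, co$samples, s)
      unique(cc$gene_id[cc$call == "hypo"])
    }
  )
  spec <- subtype_specific_sets(call_sets)
  calls_t <- call_dmrs(sc, co$samples, "TNBC")
  quad <- assign_quadrants(
    collapse_gene_calls(calls_t),
    expression_differential(co$expression, co$samples, "TNBC")
  )
  recovered <- intersect(quad$gene_id[quad$quadrant == "hypo_up"], spec$specific$TNBC)
  planted <- co$truth$planted
  target <- planted$gene_id[
    planted$subtype == "TNBC" & planted$direction == "hypo" & planted$integrated
  ]
  expect_gte(mean(target %in% recovered), 0.75)
  expect_lte(length(setdiff(recovered, target)), 1)
})
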