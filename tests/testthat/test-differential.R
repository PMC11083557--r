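test_that("delta mean is the group-mean difference and is antisymmetric", {
  expect_equal(delta_mean(c(0.2, 0.4), c(0.2, 0.4)), 0)
  expect_equal(delta_mean(c(0.8, 0.6), c(0.3, 0.5)), 0.3)
  expect_equal(delta_mean(c(0.3, 0.5), c(0.8, 0.6)), -0.3)
  expect_error(delta_mean(numeric(0), 1), "non-empty")
})

test_that("paired t-test matches the closed form and its degenerate conventions", {
  res <- paired_t_test(c(1, 2, 3), c(0, 0, 0))
  expect_equal(res$statistic, 3.4641, tolerance = 1e-4)
  expect_equal(res$p_value, 2 * pt(-2 / (1 / sqrt(3)), 2))
  expect_equal(res$p_value, 0.0742, tolerance = 1e-3)

  expect_warning(zero <- paired_t_test(c(1, 1, 1), c(1, 1, 1)), "sd = 0")
  expect_equal(zero$p_value, 1)
  expect_warning(shift <- paired_t_test(c(2, 2, 2), c(1, 1, 1)), "sd = 0")
  expect_equal(shift$p_value, 0)

  neg <- paired_t_test(c(0, 0, 0), c(1, 2, 3))
  expect_equal(neg$statistic, -res$statistic)
  expect_equal(neg$p_value, res$p_value)
})

test_that("paired t-test agrees with the reference implementation", {
  set.seed(5)
  for (rep in 1:50) {
    n <- sample(3:15, 1)
    x <- rnorm(n)
    y <- rnorm(n)
    mine <- paired_t_test(x, y)
    ref <- t.test(x, y, paired = TRUE)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-12)
  }
})

test_that("BH adjustment follows the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.5), 0.5)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(13)
  for (rep in 1:30) {
    p <- runif(sample(1:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-14)
    expect_equal(q, p.adjust(p, "BH"), tolerance = 1e-14)
    expect_true(all(q >= p - 1e-15) && all(q <= 1))
  }
})

test_that("DMR calls respect the delta and significance gates", {
  # 4 pairs; planted hyper gene with delta ~ +0.3, a noisy null, and a
  # large-delta gene with inconsistent pairs (p should fail)
  meta <- toy_samples(n_pairs = 4, subtypes = "TNBC")
  t_cols <- meta$sample[meta$tumor_normal == "tumor"]
  n_cols <- meta$sample[meta$tumor_normal == "normal"]
  m <- tibble::tibble(feature_id = c("up|CDS", "null|CDS", "wobble|CDS"))
  m[, t_cols] <- NA_real_
  m[, n_cols] <- NA_real_
  m[1, t_cols] <- as.list(c(0.72, 0.68, 0.70, 0.71))
  m[1, n_cols] <- as.list(c(0.42, 0.38, 0.40, 0.41))
  m[2, t_cols] <- as.list(c(0.50, 0.52, 0.49, 0.51))
  m[2, n_cols] <- as.list(c(0.51, 0.49, 0.52, 0.50))
  # mean paired difference -0.225 (past the delta gate) but sd so large
  # that the p gate keeps the call at ns
  m[3, t_cols] <- as.list(c(0.00, 0.70, 0.00, 0.75))
  m[3, n_cols] <- as.list(c(0.95, 0.20, 0.90, 0.30))
  attr(m, "scaled") <- TRUE

  calls <- call_dmrs(m, meta, "TNBC")
  expect_equal(calls$call, c("hyper", "ns", "ns"))
  expect_equal(calls$gene_id, c("up", "null", "wobble"))
  expect_equal(calls$region_class, rep("CDS", 3))
  expect_true(all(calls$q_value >= calls$p_value - 1e-15))
  expect_equal(calls$delta_mean[1], 0.3, tolerance = 1e-9)
})

test_that("unpaired samples abort with the orphans named", {
  meta <- toy_samples(n_pairs = 3, subtypes = "TNBC")
  meta <- meta[-2, ] # drop one normal
  m <- tibble::tibble(feature_id = "x")
  m[, meta$sample] <- as.list(runif(nrow(meta)))
  expect_error(call_dmrs(m, meta, "TNBC"), "TNBC_p1")
})

test_that("context composition counts the 2x2 partition per direction", {
  calls <- tibble::tibble(
    gene_id = sprintf("g%d", 1:10),
    region_class = rep(c("promoter", "CDS"), 5),
    call = c(rep("hypo", 9), "hyper"),
    feature_id = NA, subtype = "TNBC", delta_mean = -0.3,
    p_value = 0.01, q_value = 0.05, neg_log10_p = 2
  )
  rois <- tibble::tibble(
    gene_id = calls$gene_id,
    region_class = calls$region_class,
    cgi_class = c(rep("nonCGI", 9), "CGI")
  )
  comp <- context_composition(calls, rois)
  hypo <- comp[comp$direction == "hypo", ]
  expect_equal(sum(hypo$fraction), 1)
  expect_equal(sum(hypo$n), 9L)
  expect_equal(unique(hypo$cgi_class), "nonCGI")
  hyper <- comp[comp$direction == "hyper", ]
  expect_equal(hyper$fraction, 1)

  # direction with no calls is absent
  none <- context_composition(calls[calls$call == "hyper", ], rois)
  expect_false("hypo" %in% none$direction)

  expect_error(
    context_composition(calls, rois[-1, ]),
    "g1"
  )
})

test_that("top-variable selection ranks by SD ratio with lexicographic ties", {
  m <- tibble::tibble(
    feature_id = c("a", "b", "c"),
    s1 = c(0, 0, 0), s2 = c(3, 1, 2), s3 = c(6, 2, 4)
  )
  top <- select_top_variable(m, 2)
  expect_equal(top$feature_id, c("a", "c"))
  expect_equal(top$sd_ratio[1], 1)
  all3 <- select_top_variable(m, 3)
  expect_equal(all3$feature_id, c("a", "c", "b"))
  expect_error(select_top_variable(m, 0), "positive")
  expect_error(select_top_variable(m, 4), "exceed")

  tie <- tibble::tibble(feature_id = c("z", "y"), s1 = c(0, 0), s2 = c(1, 1))
  expect_equal(select_top_variable(tie, 1)$feature_id, "y")
})

test_that("UPGMA reproduces hand-computed merges on a 1-D instance", {
  m <- tibble::tibble(feature_id = "f", a = 0, b = 1, c = 10)
  hc <- average_linkage_cluster(m)
  expect_equal(hc$height, c(1, 9.5))
  sets <- hclust_merge_sets(hc)
  expect_equal(sets[[1]], c(1, 2))
  expect_equal(sets[[2]], c(1, 2, 3))

  dup <- tibble::tibble(feature_id = "f", a = 2, b = 2, c = 7)
  hc2 <- average_linkage_cluster(dup)
  expect_equal(hc2$height[1], 0)
  expect_error(
    average_linkage_cluster(tibble::tibble(feature_id = "f", a = NaN, b = 1)),
    "NaN"
  )
})

test_that("UPGMA agrees with the brute-force all-pairs oracle and hclust", {
  set.seed(41)
  for (rep in 1:25) {
    n_s <- sample(3:6, 1)
    pts <- matrix(rnorm(n_s * 3), n_s)
    m <- dplyr::bind_cols(
      tibble::tibble(feature_id = sprintf("f%d", 1:3)),
      tibble::as_tibble(as.data.frame(t(pts)))
    )
    names(m)[-1] <- sprintf("s%d", seq_len(n_s))
    hc <- average_linkage_cluster(m)
    oracle <- upgma_oracle(pts)
    expect_equal(hc$height, oracle$heights, tolerance = 1e-10)
    expect_equal(hclust_merge_sets(hc), oracle$merges)
    expect_true(all(diff(hc$height) >= -1e-12))
    ref <- hclust(dist(pts), method = "average")
    expect_equal(hc$height, ref$height, tolerance = 1e-10)
  }
})
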