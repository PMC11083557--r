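#' Delta mean between tumor and normal groups
#'
#' `mean(tumor) - mean(normal)`, the methylation-difference statistic on
#' the 0-1 scaled score; swapping the groups negates it.
#'
#' @param tumor,normal Numeric vectors of scores; both non-empty.
#' @return A single number.
#' @export
delta_mean <- function(tumor, normal) {
  if (!length(tumor) || !length(normal)) {
    abort("Both groups must be non-empty.")
  }
  mean(tumor) - mean(normal)
}

#' Paired two-sided t-test
#'
#' Computes `t = mean(d) / (sd(d) / sqrt(n))` on the per-pair differences
#' `d = tumor - normal` and the two-sided p-value from the t distribution
#' with `n - 1` degrees of freedom. When all differences are identical
#' (`sd = 0`) the p-value is reported as 0 if the common difference is
#' non-zero and 1 otherwise, with a warning.
#'
#' @param tumor,normal Paired numeric vectors in matching pair order,
#'   length at least 2.
#' @return A one-row tibble with `statistic`, `p_value`, `df`.
#' @examples
#' paired_t_test(c(2, 4, 6), c(1, 2, 3))
#' @export
paired_t_test <- function(tumor, normal) {
  if (length(tumor) != length(normal)) {
    abort("`tumor` and `normal` must have matching pair order (equal length).")
  }
  if (length(tumor) < 2L) abort("At least 2 pairs are required.")
  d <- tumor - normal
  n <- length(d)
  s <- sd(d)
  m <- mean(d)
  if (s == 0) {
    warn("All paired differences identical (sd = 0); degenerate p-value convention applied.")
    t_stat <- if (m == 0) 0 else sign(m) * Inf
    p <- if (m == 0) 1 else 0
  } else {
    t_stat <- m / (s / sqrt(n))
    p <- 2 * pt(-abs(t_stat), df = n - 1)
  }
  tibble::tibble(statistic = t_stat, p_value = p, df = n - 1)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q(i) = min_{j >= i} p_(j) * m / j`, capped at 1 and returned in the
#' input order.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1)) {
    abort("All p-values must lie in [0, 1].")
  }
  m <- length(p)
  if (m == 0L) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  pmin(1, cummin(m / (m:1) * p[o]))[order(o)]
}

#' Call differentially methylated genes for one subtype
#'
#' Runs the paired tumor-versus-normal comparison per feature on a scaled
#' methylation matrix: delta mean, paired t-test p, BH q, and a call of
#' `hyper` (`delta > delta_threshold` and significant), `hypo`
#' (`delta < -delta_threshold` and significant) or `ns`. Significance is
#' gated on the raw p-value by default (the study's stated criterion);
#' `gate = "q"` switches to a strict-FDR mode gated on the BH q-value.
#'
#' @param scores Scaled feature-by-sample tibble (see [minmax_scale()]).
#' @param samples Sample metadata with columns `sample`, `subtype`,
#'   `tumor_normal` (`"tumor"`/`"normal"`), `pair_id`.
#' @param subtype Which subtype to test (needs at least 2 complete pairs).
#' @param delta_threshold Absolute delta-mean cutoff on the 0-1 scale
#'   (default 0.2).
#' @param p_threshold Significance cutoff (default 0.05).
#' @param gate `"p"` (default) or `"q"`.
#' @param paired Use the paired t-test (default); `FALSE` falls back to
#'   Welch's two-sample test for unmatched designs.
#' @return A tibble with one row per feature: `feature_id`, `gene_id`,
#'   `region_class`, `subtype`, `delta_mean`, `p_value`, `q_value`,
#'   `neg_log10_p`, `call`. Ready for volcano plotting via
#'   [plot_volcano()].
#' @export
call_dmrs <- function(scores, samples, subtype,
                      delta_threshold = 0.2, p_threshold = 0.05,
                      gate = c("p", "q"), paired = TRUE) {
  gate <- match.arg(gate)
  check_feature_matrix(scores, "scores")
  if (isFALSE(attr(scores, "scaled"))) {
    abort("`scores` must be 0-1 scaled (see minmax_scale()).")
  }
  needed <- c("sample", "subtype", "tumor_normal", "pair_id")
  if (!is.data.frame(samples) || !all(needed %in% names(samples))) {
    abort(paste0("`samples` must contain columns ", paste(needed, collapse = ", "), "."))
  }
  meta <- samples[samples$subtype == subtype, , drop = FALSE]
  if (!nrow(meta)) abort(sprintf("No samples with subtype '%s'.", subtype))
  missing_cols <- setdiff(meta$sample, colnames(scores)[-1L])
  if (length(missing_cols)) {
    abort(sprintf("Samples missing from the score matrix: %s",
                  paste(missing_cols, collapse = ", ")))
  }

  tab <- table(meta$pair_id, meta$tumor_normal)
  complete <- rownames(tab)[tab[, "tumor", drop = TRUE] == 1 &
                              tab[, "normal", drop = TRUE] == 1]
  orphans <- setdiff(rownames(tab), complete)
  if (length(orphans)) {
    abort(sprintf("Unpaired samples for pair id(s): %s",
                  paste(orphans, collapse = ", ")))
  }
  if (length(complete) < 2L) abort("At least 2 tumor/normal pairs are required.")

  t_cols <- meta$sample[meta$tumor_normal == "tumor"][
    match(complete, meta$pair_id[meta$tumor_normal == "tumor"])]
  n_cols <- meta$sample[meta$tumor_normal == "normal"][
    match(complete, meta$pair_id[meta$tumor_normal == "normal"])]

  v <- feature_values(scores)
  tv <- v[, t_cols, drop = FALSE]
  nv <- v[, n_cols, drop = FALSE]
  np <- length(complete)
  delta <- rowMeans(tv) - rowMeans(nv)

  if (paired) {
    d <- tv - nv
    md <- rowMeans(d)
    sdd <- sqrt(rowSums((d - md)^2) / (np - 1))
    degen <- sdd == 0
    t_stat <- ifelse(degen, ifelse(md == 0, 0, sign(md) * Inf),
                     md / (sdd / sqrt(np)))
    p <- ifelse(degen, ifelse(md == 0, 1, 0),
                2 * pt(-abs(md / (sdd / sqrt(np))), df = np - 1))
    if (any(degen)) {
      warn(sprintf(
        "%d feature(s) had identical paired differences; degenerate p convention applied.",
        sum(degen)
      ))
    }
  } else {
    res <- apply(cbind(tv, nv), 1L, function(x) {
      ht <- stats::t.test(x[seq_len(np)], x[np + seq_len(np)])
      c(ht$statistic, ht$p.value)
    })
    t_stat <- res[1L, ]
    p <- res[2L, ]
  }

  q <- bh_adjust(p)
  gate_val <- if (gate == "p") p else q
  call <- dplyr::case_when(
    delta > delta_threshold & gate_val < p_threshold ~ "hyper",
    delta < -delta_threshold & gate_val < p_threshold ~ "hypo",
    TRUE ~ "ns"
  )

  ids <- as.character(scores[[1L]])
  parts <- strsplit(ids, "|", fixed = TRUE)
  two_part <- lengths(parts) == 2L
  gene_id <- ifelse(two_part, vapply(parts, `[`, "", 1L), ids)
  region_class <- ifelse(two_part, vapply(parts, `[`, "", 2L), NA_character_)

  tibble::tibble(
    feature_id = ids,
    gene_id = gene_id,
    region_class = region_class,
    subtype = subtype,
    delta_mean = unname(delta),
    p_value = unname(p),
    q_value = unname(q),
    neg_log10_p = -log10(unname(p)),
    call = call
  )
}

#' Genomic-context composition of DMR calls
#'
#' Tabulates, separately for hyper- and hypomethylated calls, the
#' fraction of called features in each cell of
#' `{CGI, nonCGI} x {promoter, CDS}` (the pie-chart partition). A
#' direction with no calls is simply absent from the output.
#'
#' @param calls Output of [call_dmrs()].
#' @param rois Classified ROI records with `gene_id`, `region_class`,
#'   `cgi_class`.
#' @return A tibble with `direction`, `region_class`, `cgi_class`, `n`,
#'   `fraction` (fractions sum to 1 within each direction).
#' @export
context_composition <- function(calls, rois) {
  called <- calls[calls$call %in% c("hyper", "hypo"), , drop = FALSE]
  if (!nrow(called)) {
    return(tibble::tibble(
      direction = character(), region_class = character(),
      cgi_class = character(), n = integer(), fraction = numeric()
    ))
  }
  ann <- rois[, c("gene_id", "region_class", "cgi_class")]
  joined <- dplyr::left_join(called, ann, by = c("gene_id", "region_class"))
  if (anyNA(joined$cgi_class)) {
    missing <- unique(joined$gene_id[is.na(joined$cgi_class)])
    abort(sprintf("No ROI annotation for gene(s): %s",
                  paste(head(missing, 5L), collapse = ", ")))
  }
  joined |>
    dplyr::count(direction = .data$call, .data$region_class, .data$cgi_class) |>
    dplyr::group_by(.data$direction) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
}

#' Select the most variable features
#'
#' Ranks features by `SD / SD_max` across all samples (rank-preserving
#' normalization of the per-feature standard deviation) and returns the
#' top `k`, ties broken by feature ID in lexicographic order.
#'
#' @param m Feature-by-sample tibble.
#' @param k How many features to keep (`0 < k <=` feature count).
#' @return A tibble `feature_id`, `sd`, `sd_ratio`, in descending
#'   `sd_ratio` order.
#' @export
select_top_variable <- function(m, k = 1000) {
  check_feature_matrix(m, "m")
  if (k <= 0) abort("`k` must be positive.")
  v <- feature_values(m)
  if (k > nrow(v)) abort("`k` cannot exceed the number of features.")
  sds <- apply(v, 1L, sd)
  out <- tibble::tibble(
    feature_id = as.character(m[[1L]]),
    sd = sds,
    sd_ratio = if (max(sds) > 0) sds / max(sds) else sds
  )
  out <- out[order(-out$sd_ratio, out$feature_id), , drop = FALSE]
  out[seq_len(k), , drop = FALSE]
}

#' Average-linkage (UPGMA) clustering of samples
#'
#' Agglomerative clustering of the sample columns under Euclidean
#' distance with average (UPGMA) linkage, implemented with an explicit
#' deterministic tie-break: among minimum-distance cluster pairs the one
#' with the smallest creation indices merges first. Returns a standard
#' `hclust` object (plottable, convertible to Newick via
#' `ape::as.phylo()`).
#'
#' @param m Feature-by-sample tibble with at least 2 sample columns and
#'   no missing values.
#' @return An object of class `hclust`.
#' @export
average_linkage_cluster <- function(m) {
  check_feature_matrix(m, "m")
  v <- feature_values(m)
  if (ncol(v) < 2L) abort("At least 2 samples are required.")
  if (anyNA(v) || any(!is.finite(v))) abort("Matrix contains NaN or non-finite values.")
  d <- as.matrix(stats::dist(t(v), method = "euclidean"))
  upgma(d, colnames(v))
}

# UPGMA on a symmetric distance matrix. Cluster "creation index" order:
# the n leaves first, then merged clusters in merge order; ties pick the
# lexicographically smallest (i, j) pair of creation indices.
upgma <- function(d, labels) {
  n <- nrow(d)
  sizes <- rep(1L, n)
  codes <- -seq_len(n) # hclust codes: negative leaf, positive merge row
  active <- seq_len(n) # creation order of live clusters
  cur <- d
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (step in seq_len(n - 1L)) {
    k <- length(active)
    best <- c(NA_integer_, NA_integer_)
    best_d <- Inf
    for (i in seq_len(k - 1L)) {
      for (j in seq((i + 1L), k)) {
        if (cur[i, j] < best_d) {
          best_d <- cur[i, j]
          best <- c(i, j)
        }
      }
    }
    i <- best[1L]; j <- best[2L]
    a <- codes[active[i]]; b <- codes[active[j]]
    # hclust convention: singletons (negative) before merges, else ascending
    pair <- if ((a < 0 && b < 0 && a > b) || (a > 0 && b > 0 && a > b) ||
                (a > 0 && b < 0)) c(b, a) else c(a, b)
    merge[step, ] <- pair
    height[step] <- best_d

    new_row <- (sizes[active[i]] * cur[i, ] + sizes[active[j]] * cur[j, ]) /
      (sizes[active[i]] + sizes[active[j]])
    new_row <- new_row[-c(i, j)]

    new_size <- sizes[active[i]] + sizes[active[j]]
    sizes <- c(sizes, new_size)
    codes <- c(codes, step)
    keep <- setdiff(seq_len(k), c(i, j))
    cur <- cur[keep, keep, drop = FALSE]
    cur <- rbind(cbind(cur, new_row), c(new_row, 0))
    active <- c(active[keep], n + step)
  }

  order_leaves <- function(i) {
    if (i < 0) return(-i)
    c(order_leaves(merge[i, 1L]), order_leaves(merge[i, 2L]))
  }
  structure(
    list(
      merge = merge, height = height,
      order = order_leaves(n - 1L),
      labels = labels, method = "average",
      dist.method = "euclidean"
    ),
    class = "hclust"
  )
}
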