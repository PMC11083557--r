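#' Differential expression between matched tumor and normal samples
#'
#' Per-gene log2 fold change (`mean(tumor) - mean(normal)` on log2
#' intensities), paired t-test p-value and BH q-value, reusing the same
#' primitives as the methylation comparison.
#'
#' @param expr Gene-by-sample tibble of log2 intensities (first column
#'   gene IDs).
#' @param samples Sample metadata (`sample`, `subtype`, `tumor_normal`,
#'   `pair_id`).
#' @param subtype Subtype to test.
#' @param paired Paired t-test (default) or Welch's test.
#' @return A tibble `gene_id`, `log2_fold_change`, `p_value`, `q_value`.
#' @export
expression_differential <- function(expr, samples, subtype, paired = TRUE) {
  res <- call_dmrs(expr, samples, subtype,
    delta_threshold = Inf, p_threshold = 0, paired = paired
  )
  tibble::tibble(
    gene_id = res$feature_id,
    log2_fold_change = res$delta_mean,
    p_value = res$p_value,
    q_value = res$q_value
  )
}

#' Assign genes to methylation-expression quadrants
#'
#' Joint classification of each gene by methylation call and expression
#' change: `hypo_up`, `hypo_down`, `hyper_up`, `hyper_down`, or `none`
#' when the methylation call is `ns` or `|log2FC|` falls below the
#' threshold. Expression significance can additionally be required via
#' `expr_p_threshold`.
#'
#' @param meth_calls One methylation call per gene (collapse multi-region
#'   calls first with [collapse_gene_calls()]); duplicate gene records
#'   are an error.
#' @param expr Output of [expression_differential()]; one record per
#'   gene.
#' @param fc_threshold_log2 Absolute log2 fold-change threshold (default
#'   `log2(1.2)`).
#' @param expr_p_threshold Optional expression p-value gate (default 0.05;
#'   use `NULL` to classify on fold change alone).
#' @return A tibble `gene_id`, `call`, `delta_mean`, `log2_fold_change`,
#'   `expr_p_value`, `quadrant`.
#' @export
assign_quadrants <- function(meth_calls, expr, fc_threshold_log2 = log2(1.2),
                             expr_p_threshold = 0.05) {
  if (anyDuplicated(meth_calls$gene_id)) {
    abort("Duplicate gene records in `meth_calls`; collapse to one call per gene first.")
  }
  if (anyDuplicated(expr$gene_id)) {
    abort("Duplicate gene records in `expr`.")
  }
  joined <- dplyr::inner_join(
    meth_calls[, c("gene_id", "call", "delta_mean")],
    dplyr::rename(expr[, c("gene_id", "log2_fold_change", "p_value")],
      expr_p_value = "p_value"
    ),
    by = "gene_id"
  )
  fc <- joined$log2_fold_change
  expr_sig <- if (is.null(expr_p_threshold)) TRUE else joined$expr_p_value < expr_p_threshold
  changed <- abs(fc) >= fc_threshold_log2 & expr_sig
  joined$quadrant <- dplyr::case_when(
    joined$call == "hypo" & changed & fc > 0 ~ "hypo_up",
    joined$call == "hypo" & changed & fc < 0 ~ "hypo_down",
    joined$call == "hyper" & changed & fc > 0 ~ "hyper_up",
    joined$call == "hyper" & changed & fc < 0 ~ "hyper_down",
    TRUE ~ "none"
  )
  joined
}

#' Collapse per-region methylation calls to one call per gene
#'
#' A gene with any called region keeps the called row with the largest
#' absolute delta mean (ties: smaller p-value, then promoter before CDS);
#' a gene with no called region keeps its smallest-p row with call `ns`.
#'
#' @param calls Output of [call_dmrs()] (possibly several regions per
#'   gene).
#' @return One row per gene.
#' @export
collapse_gene_calls <- function(calls) {
  calls |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::arrange(
      .data$call == "ns", -abs(.data$delta_mean), .data$p_value,
      .data$region_class,
      .by_group = TRUE
    ) |>
    dplyr::slice(1L) |>
    dplyr::ungroup()
}

#' Subtype-specific and shared call sets
#'
#' Exact set algebra over per-subtype call sets: a gene is *specific* to
#' a subtype when it is called in exactly that subtype, and *shared*
#' when called in all subtypes.
#'
#' @param call_sets Named list (one element per subtype, at least two) of
#'   character vectors of called gene IDs.
#' @return A list of class `specificity_sets` with elements `specific`
#'   (named list per subtype) and `shared` (character vector).
#' @examples
#' subtype_specific_sets(list(A = c("g1", "g2"), B = c("g2", "g3")))
#' @export
subtype_specific_sets <- function(call_sets) {
  if (!is.list(call_sets) || length(call_sets) < 2L || is.null(names(call_sets))) {
    abort("`call_sets` must be a named list with at least two subtypes.")
  }
  call_sets <- purrr::map(call_sets, unique)
  specific <- purrr::imap(call_sets, function(s, name) {
    others <- unlist(call_sets[setdiff(names(call_sets), name)], use.names = FALSE)
    setdiff(s, others)
  })
  shared <- purrr::reduce(call_sets, intersect)
  structure(list(specific = specific, shared = shared), class = "specificity_sets")
}

#' @export
print.specificity_sets <- function(x, ...) {
  cat("<specificity_sets>\n")
  for (s in names(x$specific)) {
    cat(sprintf("  %s-specific: %d\n", s, length(x$specific[[s]])))
  }
  cat(sprintf("  shared: %d\n", length(x$shared)))
  invisible(x)
}

#' Tidy a specificity-set object
#'
#' @param x A `specificity_sets` object.
#' @param ... Unused.
#' @return A tibble `gene_id`, `category` (subtype label or `"shared"`).
#' @export
tidy.specificity_sets <- function(x, ...) {
  parts <- c(
    unname(purrr::imap(x$specific, ~ tibble::tibble(gene_id = .x, category = .y))),
    list(tibble::tibble(
      gene_id = x$shared, category = rep("shared", length(x$shared))
    ))
  )
  dplyr::bind_rows(parts)
}

#' Screen quadrant candidates for subtype specificity
#'
#' For each candidate gene, computes a median-margin specificity score in
#' an independent validation cohort: the difference between the median of
#' the target subtype and the median of all other subtypes, separately
#' for methylation (sign must match the methylation call) and expression
#' (sign must match the quadrant's expression direction). Candidates pass
#' when both margins exceed their thresholds with the right sign, and are
#' ranked by the product of absolute margins.
#'
#' @param quadrants Quadrant table ([assign_quadrants()]) restricted to
#'   genes of interest (`quadrant != "none"` rows are screened).
#' @param meth Validation methylation tibble (features or genes by
#'   samples, scaled); rows matched to genes via the ID prefix before
#'   `"|"`, so either `gene` or `gene|region` keys work.
#' @param expr Validation expression tibble (genes by samples).
#' @param sample_subtypes Named character vector or tibble
#'   (`sample`, `subtype`) giving each validation sample's subtype.
#' @param target_subtype The subtype whose specificity is screened.
#' @param meth_margin,expr_margin Minimum absolute median margins.
#' @return A tibble `gene_id`, `quadrant`, `meth_margin`, `expr_margin`,
#'   `passes`, `score`, ranked by `score` among passing genes.
#' @export
candidate_screen <- function(quadrants, meth, expr, sample_subtypes,
                             target_subtype, meth_margin = 0.1,
                             expr_margin = 0.5) {
  if (is.data.frame(sample_subtypes)) {
    sample_subtypes <- setNames(sample_subtypes$subtype, sample_subtypes$sample)
  }
  if (!target_subtype %in% sample_subtypes) {
    abort(sprintf("No validation samples with subtype '%s'.", target_subtype))
  }
  if (length(unique(sample_subtypes)) < 2L) {
    abort("Validation cohort must contain at least 2 subtypes.")
  }
  cand <- quadrants[quadrants$quadrant != "none", , drop = FALSE]

  margin_for <- function(mat, gene) {
    ids <- sub("\\|.*$", "", as.character(mat[[1L]]))
    rows <- which(ids == gene)
    if (!length(rows)) return(NA_real_)
    vals <- colMeans(feature_values(mat)[rows, , drop = FALSE])
    st <- sample_subtypes[names(vals)]
    median(vals[st == target_subtype]) - median(vals[st != target_subtype])
  }

  res <- purrr::map_dfr(seq_len(nrow(cand)), function(i) {
    gene <- cand$gene_id[i]
    quad <- cand$quadrant[i]
    mm <- margin_for(meth, gene)
    em <- margin_for(expr, gene)
    tibble::tibble(gene_id = gene, quadrant = quad,
                   meth_margin = mm, expr_margin = em)
  })
  skipped <- res$gene_id[is.na(res$meth_margin) | is.na(res$expr_margin)]
  if (length(skipped)) {
    warn(sprintf("Gene(s) absent from the validation tables, skipped: %s",
                 paste(skipped, collapse = ", ")))
    res <- res[!res$gene_id %in% skipped, , drop = FALSE]
  }
  if (!nrow(res)) {
    return(tibble::tibble(
      gene_id = character(), quadrant = character(), meth_margin = numeric(),
      expr_margin = numeric(), passes = logical(), score = numeric()
    ))
  }
  meth_sign <- ifelse(grepl("^hypo", res$quadrant), -1, 1)
  expr_sign <- ifelse(grepl("up$", res$quadrant), 1, -1)
  res$passes <- sign(res$meth_margin) == meth_sign &
    sign(res$expr_margin) == expr_sign &
    abs(res$meth_margin) >= meth_margin &
    abs(res$expr_margin) >= expr_margin
  res$score <- ifelse(res$passes, abs(res$meth_margin) * abs(res$expr_margin), 0)
  dplyr::arrange(res, dplyr::desc(.data$passes), dplyr::desc(.data$score), .data$gene_id)
}
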