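#' Absolute methylation scores from ROI read counts
#'
#' Converts raw enrichment counts to a depth-, length- and
#' CpG-density-normalized score:
#' \deqn{ams_{g,s} = \frac{c_{g,s} / (L_s/10^6)}{\ell_g/10^3} \Big/
#'       \frac{n^{CpG}_g + k}{\mathrm{median}_g(n^{CpG}_g + k)}}
#' i.e. reads per kb per million mapped reads, divided by the region's
#' CpG weight relative to the cohort median. With `cpg_counts = NULL`
#' the CpG correction is off and the score reduces to an RPKM-like
#' quantity.
#'
#' @param counts Feature-by-sample count tibble: first column feature
#'   IDs, remaining columns one per sample, non-negative integers.
#' @param roi_lengths Region lengths in bp, one per feature (named or in
#'   row order); all positive.
#' @param library_sizes Total mapped reads per sample (named or in column
#'   order); all positive.
#' @param cpg_counts CpGs per region, or `NULL` to disable the CpG
#'   correction.
#' @param cpg_pseudocount Added to every CpG count before weighting so
#'   CpG-free regions stay finite (default 1).
#' @return An unscaled methylation-score tibble with the same shape as
#'   `counts` (attribute `scaled = FALSE`).
#' @examples
#' counts <- tibble::tibble(feature_id = "r1", s1 = 100L)
#' compute_ams(counts, roi_lengths = 1000, library_sizes = 1e6)
#' @export
compute_ams <- function(counts, roi_lengths, library_sizes,
                        cpg_counts = NULL, cpg_pseudocount = 1) {
  check_feature_matrix(counts, "counts")
  m <- feature_values(counts)
  n_feat <- nrow(m)
  n_samp <- ncol(m)

  roi_lengths <- align_by_names(roi_lengths, counts[[1L]], n_feat, "roi_lengths")
  library_sizes <- align_by_names(library_sizes, colnames(m), n_samp, "library_sizes")
  if (any(roi_lengths <= 0)) abort("Zero or negative ROI length.")
  if (any(library_sizes <= 0)) abort("Zero or negative library size.")
  if (any(m < 0)) abort("`counts` must be non-negative.")

  ams <- sweep(m, 2L, library_sizes / 1e6, `/`)
  ams <- ams / (roi_lengths / 1e3)
  if (!is.null(cpg_counts)) {
    cpg_counts <- align_by_names(cpg_counts, counts[[1L]], n_feat, "cpg_counts")
    w <- cpg_counts + cpg_pseudocount
    if (any(w <= 0)) abort("CpG count plus pseudocount must be positive.")
    ams <- ams / (w / median(w))
  }
  out <- feature_tibble(counts[[1L]], ams, id_col = names(counts)[1L])
  attr(out, "scaled") <- FALSE
  out
}

align_by_names <- function(x, keys, n, arg) {
  if (!is.null(names(x))) {
    missing <- setdiff(keys, names(x))
    if (length(missing)) {
      abort(sprintf("`%s` is missing entries for: %s", arg,
                    paste(head(missing, 5L), collapse = ", ")))
    }
    x <- x[keys]
  }
  if (length(x) != n) {
    abort(sprintf("`%s` must have length %d (got %d).", arg, n, length(x)))
  }
  unname(as.numeric(x))
}

#' Scale each sample's scores to the 0-1 range
#'
#' Per sample column, maps `x -> (x - min) / (max - min)`. A constant
#' column cannot be ranged and is mapped to all zeros with a warning.
#' The transform is invariant to positive affine changes of a column and
#' preserves within-sample rank order.
#'
#' @param m An unscaled methylation-score tibble from [compute_ams()]
#'   (or any feature-by-sample tibble).
#' @return The scaled tibble (attribute `scaled = TRUE`).
#' @export
minmax_scale <- function(m) {
  check_feature_matrix(m, "m")
  if (isTRUE(attr(m, "scaled"))) {
    abort("`m` is already scaled.")
  }
  v <- feature_values(m)
  rng <- apply(v, 2L, range)
  constant <- rng[1L, ] == rng[2L, ]
  if (any(constant)) {
    warn(sprintf(
      "Constant sample column(s) mapped to 0: %s",
      paste(colnames(v)[constant], collapse = ", ")
    ))
  }
  denom <- ifelse(constant, 1, rng[2L, ] - rng[1L, ])
  scaled <- sweep(v, 2L, rng[1L, ], `-`)
  scaled <- sweep(scaled, 2L, denom, `/`)
  scaled[, constant] <- 0
  out <- feature_tibble(m[[1L]], scaled, id_col = names(m)[1L])
  attr(out, "scaled") <- TRUE
  out
}
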