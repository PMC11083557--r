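#' Configure the synthetic paired-cohort simulation
#'
#' Defines the study conditions for [simulate_cohort()]: a paired
#' tumor/normal MBD-seq-style cohort across breast-cancer intrinsic
#' subtypes, with subtype-specific hyper-/hypomethylated genes planted at a
#' known latent effect size, a subset of planted genes coupled to
#' expression, and an independent clinical validation cohort whose hazard
#' depends on a designated marker gene's methylation/expression state.
#'
#' The latent state of every gene region is a methylation fraction on the
#' 0-1 scale. Planted regions shift that fraction by exactly
#' `+effect_size` (hypermethylated) or `-effect_size` (hypomethylated) in
#' tumor samples of the carrying subtype; base fractions are drawn so the
#' shift never hits the clipping bounds, so the planted tumor-normal
#' latent difference equals the configured effect exactly in expectation.
#' Observed counts are negative binomial around
#' `fraction x region length x library depth x CpG weight`.
#'
#' @param n_genes Number of simulated genes. Each gene contributes one
#'   promoter and one CDS region of interest.
#' @param n_pairs_per_subtype Matched tumor/normal pairs per subtype.
#' @param subtypes Subtype labels; defaults to the four intrinsic
#'   breast-cancer subtypes.
#' @param n_planted_hyper,n_planted_hypo Subtype-specific planted gene
#'   counts (per subtype, disjoint across subtypes).
#' @param n_shared Genes planted as hypomethylated in *all* subtypes.
#' @param n_integrated_hyper,n_integrated_hypo How many of each subtype's
#'   planted genes are coupled to expression (hyper -> down, hypo -> up).
#'   Must not exceed the corresponding planted count.
#' @param effect_size Latent methylation-fraction shift in `[0, 1)`.
#' @param dispersion Negative-binomial dispersion of the region counts
#'   (`variance = mu + dispersion * mu^2`); `0` gives Poisson counts.
#' @param expr_effect Log2 expression shift for integrated genes at the
#'   full planted methylation shift.
#' @param hazard_ratio Relative hazard of the planted high-risk clinical
#'   group (marker-gene hypomethylated and highly expressed).
#' @param baseline_hazard Baseline exponential event rate (per time unit)
#'   of the clinical cohort.
#' @param censoring_rate Expected censored fraction in `[0, 1)`.
#' @param n_clinical Size of the independent clinical validation cohort.
#' @param depth_factor Multiplier on expected counts; 1 corresponds to one
#'   expected read per kb per million mapped reads at fraction 1.
#' @param subject_sd SD of the per-gene subject effect shared by both
#'   members of a pair (cancels in paired differences).
#' @param sample_noise_sd SD of the residual per-sample latent noise.
#' @param expr_noise_sd SD of log2 expression noise.
#' @param p_cds_target Probability that a planted gene's shifted region is
#'   its CDS rather than its promoter.
#' @param seed Integer seed; identical config implies bitwise-identical
#'   simulation output.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_cohort()]
#' @export
sim_config <- function(n_genes = 500L,
                       n_pairs_per_subtype = 10L,
                       subtypes = c("LumA", "LumB", "HER2", "TNBC"),
                       n_planted_hyper = 15L,
                       n_planted_hypo = 15L,
                       n_shared = 5L,
                       n_integrated_hyper = 10L,
                       n_integrated_hypo = 10L,
                       effect_size = 0.3,
                       dispersion = 0.005,
                       expr_effect = 1.5,
                       hazard_ratio = 3,
                       baseline_hazard = 0.05,
                       censoring_rate = 0.2,
                       n_clinical = 200L,
                       depth_factor = 5,
                       subject_sd = 0.05,
                       sample_noise_sd = 0.01,
                       expr_noise_sd = 0.4,
                       p_cds_target = 0.62,
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    n_pairs_per_subtype = as.integer(n_pairs_per_subtype),
    subtypes = as.character(subtypes),
    n_planted_hyper = as.integer(n_planted_hyper),
    n_planted_hypo = as.integer(n_planted_hypo),
    n_shared = as.integer(n_shared),
    n_integrated_hyper = as.integer(n_integrated_hyper),
    n_integrated_hypo = as.integer(n_integrated_hypo),
    effect_size = effect_size,
    dispersion = dispersion,
    expr_effect = expr_effect,
    hazard_ratio = hazard_ratio,
    baseline_hazard = baseline_hazard,
    censoring_rate = censoring_rate,
    n_clinical = as.integer(n_clinical),
    depth_factor = depth_factor,
    subject_sd = subject_sd,
    sample_noise_sd = sample_noise_sd,
    expr_noise_sd = expr_noise_sd,
    p_cds_target = p_cds_target,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stop_bound <- function(msg) abort(paste0("Invalid simulation config: ", msg))
  if (cfg$n_genes < 1L) stop_bound("`n_genes` must be a positive integer.")
  if (cfg$n_pairs_per_subtype < 1L) {
    stop_bound("`n_pairs_per_subtype` must be a positive integer.")
  }
  if (length(cfg$subtypes) < 1L || anyDuplicated(cfg$subtypes)) {
    stop_bound("`subtypes` must be a non-empty list of distinct labels.")
  }
  if (cfg$n_planted_hyper < 0L || cfg$n_planted_hypo < 0L || cfg$n_shared < 0L) {
    stop_bound("planted gene counts must be non-negative.")
  }
  planted_total <- length(cfg$subtypes) * (cfg$n_planted_hyper + cfg$n_planted_hypo) +
    cfg$n_shared
  if (planted_total > cfg$n_genes) {
    stop_bound(sprintf(
      "violated bound n_subtypes*(n_planted_hyper + n_planted_hypo) + n_shared <= n_genes (%d > %d).",
      planted_total, cfg$n_genes
    ))
  }
  if (cfg$n_integrated_hyper > cfg$n_planted_hyper ||
      cfg$n_integrated_hypo > cfg$n_planted_hypo) {
    stop_bound("integrated gene counts cannot exceed the planted counts.")
  }
  if (cfg$effect_size < 0 || cfg$effect_size >= 1) {
    stop_bound("violated bound effect_size in [0, 1).")
  }
  if (cfg$dispersion < 0) stop_bound("`dispersion` must be non-negative.")
  if (cfg$hazard_ratio <= 0) stop_bound("violated bound hazard_ratio > 0.")
  if (cfg$baseline_hazard <= 0) stop_bound("`baseline_hazard` must be positive.")
  if (cfg$censoring_rate < 0 || cfg$censoring_rate >= 1) {
    stop_bound("violated bound censoring_rate in [0, 1).")
  }
  if (cfg$n_clinical < 2L) stop_bound("`n_clinical` must be at least 2.")
  if (cfg$p_cds_target < 0 || cfg$p_cds_target > 1) {
    stop_bound("`p_cds_target` must lie in [0, 1].")
  }
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf(
    "  %d genes, %d pairs/subtype across %s\n",
    x$n_genes, x$n_pairs_per_subtype, paste(x$subtypes, collapse = "/")
  ))
  cat(sprintf(
    "  planted per subtype: %d hyper / %d hypo (+%d shared hypo), effect %.2f\n",
    x$n_planted_hyper, x$n_planted_hypo, x$n_shared, x$effect_size
  ))
  cat(sprintf(
    "  clinical cohort n=%d, hazard ratio %.2f, censoring %.2f, seed %d\n",
    x$n_clinical, x$hazard_ratio, x$censoring_rate, x$seed
  ))
  invisible(x)
}
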