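#' Simulate a paired tumor/normal methylation-expression cohort
#'
#' Generates all of the inputs the pipeline consumes, with known planted
#' truth: an ROI read-count matrix over promoter and CDS regions, sample
#' metadata (subtype, tumor/normal, pairing), gene models and a CpG-island
#' track, a log2 expression matrix whose planted "integrated" genes
#' anti-covary with methylation, and an independent clinical cohort whose
#' hazard depends on the designated marker gene's joint
#' methylation/expression state.
#'
#' Counts are negative binomial with mean
#' `fraction x (region length / 1e3) x (library size / 1e6) x depth_factor x CpG weight`,
#' where the CpG weight is the region's CpG count (plus one) divided by
#' the cohort median. Subject-level per-gene effects are shared by both
#' members of a matched pair, so they cancel in paired differences;
#' residual per-sample noise and count dispersion remain.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `methyl_cohort` with elements `counts`,
#'   `samples`, `genes`, `cgis`, `rois`, `expression`, `clinical`,
#'   `truth` (class `planted_truth`) and `config`.
#' @examples
#' cohort <- simulate_cohort(sim_config(n_genes = 60, n_pairs_per_subtype = 4))
#' dim(cohort$counts)
#' cohort$truth$marker
#' @export
simulate_cohort <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) {
    abort("`config` must be built with sim_config().")
  }
  config <- validate_sim_config(config)
  with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(cfg) {
  n <- cfg$n_genes
  subtypes <- cfg$subtypes

  ## --- gene models on a small synthetic genome -------------------------
  n_chrom <- min(4L, n)
  chrom <- paste0("chr", ((seq_len(n) - 1L) %% n_chrom) + 1L)
  idx_in_chrom <- stats::ave(seq_len(n), chrom, FUN = seq_along)
  slot <- 10000 + (idx_in_chrom - 1L) * 100000
  strand <- rep_len(c("+", "-"), n)
  cds_len <- sample(1000:4000, n, replace = TRUE)
  cds_start <- slot + 5000
  cds_end <- cds_start + cds_len
  tss <- ifelse(strand == "+", cds_start - 200L, cds_end + 200L)
  genes <- tibble::tibble(
    gene_id = sprintf("g%04d", seq_len(n)),
    chrom = chrom, strand = strand,
    tss = as.integer(tss),
    cds_start = as.integer(cds_start), cds_end = as.integer(cds_end)
  )

  ## --- CpG island track -------------------------------------------------
  prom_cgi <- runif(n) < 0.6
  cds_cgi <- runif(n) < 0.15
  cgis <- dplyr::bind_rows(
    tibble::tibble(
      chrom = genes$chrom[prom_cgi],
      start = genes$tss[prom_cgi] - 800L,
      end = genes$tss[prom_cgi] + 800L
    ),
    tibble::tibble(
      chrom = genes$chrom[cds_cgi],
      start = as.integer((genes$cds_start[cds_cgi] + genes$cds_end[cds_cgi]) / 2) - 300L,
      end = as.integer((genes$cds_start[cds_cgi] + genes$cds_end[cds_cgi]) / 2) + 300L
    )
  )
  cgis <- dplyr::arrange(cgis, .data$chrom, .data$start)

  rois <- classify_cgi(build_rois(genes), cgis)
  rois$feature_id <- paste(rois$gene_id, rois$region_class, sep = "|")
  rois$length <- rois$end - rois$start
  rois$cpg_count <- ifelse(
    rois$cgi_class == "CGI",
    40L + rpois(nrow(rois), 30),
    1L + rpois(nrow(rois), 12)
  )

  ## --- planted truth ----------------------------------------------------
  pool <- sample(genes$gene_id)
  take <- function(k) {
    if (k == 0L) return(character(0))
    out <- pool[seq_len(k)]
    pool <<- pool[-seq_len(k)]
    out
  }
  planted <- list()
  for (s in subtypes) {
    hyper <- take(cfg$n_planted_hyper)
    hypo <- take(cfg$n_planted_hypo)
    planted[[s]] <- list(hyper = hyper, hypo = hypo)
  }
  shared <- take(cfg$n_shared)

  planted_parts <- unname(purrr::imap(planted, function(p, s) {
    tibble::tibble(
      gene_id = c(p$hyper, p$hypo),
      subtype = s,
      direction = rep(c("hyper", "hypo"), c(length(p$hyper), length(p$hypo))),
      integrated = c(
        seq_along(p$hyper) <= cfg$n_integrated_hyper,
        seq_along(p$hypo) <= cfg$n_integrated_hypo
      )
    )
  }))
  if (length(shared)) {
    planted_parts <- c(planted_parts, list(tibble::tibble(
      gene_id = shared, subtype = "shared",
      direction = "hypo", integrated = FALSE
    )))
  }
  planted_tbl <- dplyr::bind_rows(planted_parts)
  if (nrow(planted_tbl)) {
    planted_tbl$target_region <- ifelse(
      runif(nrow(planted_tbl)) < cfg$p_cds_target, "CDS", "promoter"
    )
    planted_tbl$coupling <- ifelse(
      !planted_tbl$integrated, "none",
      ifelse(planted_tbl$direction == "hypo", "up", "down")
    )
  } else {
    planted_tbl$target_region <- character()
    planted_tbl$coupling <- character()
  }

  target_subtype <- if ("TNBC" %in% subtypes) "TNBC" else subtypes[length(subtypes)]
  marker_pool <- planted_tbl$gene_id[
    planted_tbl$subtype == target_subtype &
      planted_tbl$direction == "hypo" & planted_tbl$integrated
  ]
  marker <- if (length(marker_pool)) {
    list(
      gene_id = marker_pool[[1L]],
      rule = risk_rule(marker_pool[[1L]], "hypo", "high"),
      subtype = target_subtype
    )
  } else {
    NULL
  }

  truth <- structure(
    list(
      specific_hyper = purrr::map(planted, "hyper"),
      specific_hypo = purrr::map(planted, "hypo"),
      shared = shared,
      planted = planted_tbl,
      marker = marker,
      target_subtype = target_subtype
    ),
    class = "planted_truth"
  )

  ## --- latent methylation fractions ------------------------------------
  n_feat <- nrow(rois)
  base_frac <- 0.05 + 0.9 * rbeta(n_feat, 0.7, 0.7)
  # planted target regions get bases that leave headroom for the shift,
  # so the planted latent difference is exactly +/- effect_size
  eff <- cfg$effect_size
  feat_key <- setNames(seq_len(n_feat), rois$feature_id)
  planted_feat <- if (nrow(planted_tbl)) {
    paste(planted_tbl$gene_id, planted_tbl$target_region, sep = "|")
  } else {
    character()
  }
  if (length(planted_feat)) {
    ih <- feat_key[planted_feat[planted_tbl$direction == "hyper"]]
    il <- feat_key[planted_feat[planted_tbl$direction == "hypo"]]
    base_frac[ih] <- runif(length(ih), 0.05, max(0.05, 0.93 - eff))
    base_frac[il] <- runif(length(il), min(0.95, eff + 0.07), 0.95)
  }

  ## --- samples ----------------------------------------------------------
  samples <- tidyr::expand_grid(
    subtype = subtypes,
    pair = seq_len(cfg$n_pairs_per_subtype),
    tumor_normal = c("tumor", "normal")
  )
  samples$pair_id <- sprintf("%s_p%02d", samples$subtype, samples$pair)
  samples$sample <- sprintf(
    "%s_%s%02d", samples$subtype,
    ifelse(samples$tumor_normal == "tumor", "T", "N"), samples$pair
  )
  samples <- samples[, c("sample", "subtype", "tumor_normal", "pair_id")]
  n_samp <- nrow(samples)

  # subtype x direction shift per feature (only planted target features)
  shift <- matrix(0, n_feat, length(subtypes),
    dimnames = list(rois$feature_id, subtypes)
  )
  if (nrow(planted_tbl)) {
    for (k in seq_len(nrow(planted_tbl))) {
      row <- planted_tbl[k, ]
      sgn <- if (row$direction == "hyper") eff else -eff
      carry <- if (row$subtype == "shared") subtypes else row$subtype
      shift[feat_key[[paste(row$gene_id, row$target_region, sep = "|")]], carry] <- sgn
    }
  }

  pair_ids <- unique(samples$pair_id)
  subj_eff <- matrix(rnorm(n_feat * length(pair_ids), 0, cfg$subject_sd),
    n_feat, length(pair_ids),
    dimnames = list(NULL, pair_ids)
  )
  frac <- matrix(0, n_feat, n_samp, dimnames = list(rois$feature_id, samples$sample))
  for (j in seq_len(n_samp)) {
    sh <- if (samples$tumor_normal[j] == "tumor") shift[, samples$subtype[j]] else 0
    frac[, j] <- base_frac + subj_eff[, samples$pair_id[j]] + sh +
      rnorm(n_feat, 0, cfg$sample_noise_sd)
  }
  frac <- pmin(pmax(frac, 0.01), 0.99)

  ## --- counts -----------------------------------------------------------
  library_sizes <- round(runif(n_samp, 2.2e7, 2.8e7))
  names(library_sizes) <- samples$sample
  cw <- rois$cpg_count + 1
  cw <- cw / median(cw)
  mu <- frac * (rois$length / 1e3) * cw * cfg$depth_factor
  mu <- sweep(mu, 2L, library_sizes / 1e6, `*`)
  counts_m <- if (cfg$dispersion > 0) {
    matrix(rnbinom(length(mu), mu = mu, size = 1 / cfg$dispersion),
      n_feat, n_samp, dimnames = dimnames(mu)
    )
  } else {
    matrix(rpois(length(mu), mu), n_feat, n_samp, dimnames = dimnames(mu))
  }
  counts <- feature_tibble(rois$feature_id, counts_m)

  ## --- expression (log2 intensities) ------------------------------------
  base_expr <- rnorm(n, 8, 1.5)
  names(base_expr) <- genes$gene_id
  slope <- if (eff > 0) cfg$expr_effect / eff else 0
  expr_m <- matrix(rep(base_expr, n_samp), n, n_samp,
    dimnames = list(genes$gene_id, samples$sample)
  )
  if (nrow(planted_tbl)) {
    coupled <- planted_tbl[planted_tbl$integrated, ]
    for (k in seq_len(nrow(coupled))) {
      row <- coupled[k, ]
      fi <- feat_key[[paste(row$gene_id, row$target_region, sep = "|")]]
      expr_m[row$gene_id, ] <- base_expr[[row$gene_id]] -
        slope * (frac[fi, ] - base_frac[fi])
    }
  }
  expr_m <- expr_m + matrix(rnorm(n * n_samp, 0, cfg$expr_noise_sd), n, n_samp)
  expression <- feature_tibble(genes$gene_id, expr_m, id_col = "gene_id")

  ## --- independent clinical validation cohort ---------------------------
  clinical <- simulate_clinical_cohort(cfg, truth, base_frac, base_expr, feat_key)

  structure(
    list(
      counts = counts, samples = samples, genes = genes, cgis = cgis,
      rois = tibble::as_tibble(rois), expression = expression,
      clinical = clinical, truth = truth,
      library_sizes = library_sizes, config = cfg
    ),
    class = "methyl_cohort"
  )
}

# Marker-driven survival cohort: methylation and expression of the marker
# gene follow the same latent model as the discovery cohort, hazard is
# multiplied for subjects in the planted high-risk state (marker
# hypomethylated AND highly expressed).
simulate_clinical_cohort <- function(cfg, truth, base_frac, base_expr, feat_key) {
  m <- cfg$n_clinical
  subject_subtype <- sample(cfg$subtypes, m, replace = TRUE)
  if (is.null(truth$marker)) {
    meth <- pmin(pmax(rnorm(m, 0.5, 0.15), 0.01), 0.99)
    expr <- rnorm(m, 8, 1)
    high_risk <- rep(FALSE, m)
  } else {
    fi <- feat_key[[paste(
      truth$marker$gene_id,
      truth$planted$target_region[truth$planted$gene_id == truth$marker$gene_id][1L],
      sep = "|"
    )]]
    b <- base_frac[fi]
    shift <- ifelse(subject_subtype == truth$marker$subtype, -cfg$effect_size, 0)
    meth <- pmin(pmax(b + shift + rnorm(m, 0, 0.05), 0.01), 0.99)
    slope <- if (cfg$effect_size > 0) cfg$expr_effect / cfg$effect_size else 0
    expr <- base_expr[[truth$marker$gene_id]] - slope * (meth - b) +
      rnorm(m, 0, cfg$expr_noise_sd)
    high_risk <- meth <= median(meth) & expr > median(expr)
  }
  rate <- cfg$baseline_hazard * ifelse(high_risk, cfg$hazard_ratio, 1)
  event_time <- rexp(m, rate)
  if (cfg$censoring_rate > 0) {
    cens_time <- rexp(m, rate * cfg$censoring_rate / (1 - cfg$censoring_rate))
    time <- pmin(event_time, cens_time)
    event <- as.integer(event_time <= cens_time)
  } else {
    time <- event_time
    event <- rep(1L, m)
  }
  tibble::tibble(
    subject_id = sprintf("s%04d", seq_len(m)),
    subtype = subject_subtype,
    marker_methylation = meth,
    marker_expression = as.numeric(expr),
    time = time,
    event = event
  )
}

#' @export
print.planted_truth <- function(x, ...) {
  cat("<planted_truth>\n")
  cat(sprintf(
    "  %d planted genes (%d shared); marker: %s\n",
    nrow(x$planted), length(x$shared),
    if (is.null(x$marker)) "none" else x$marker$gene_id
  ))
  invisible(x)
}

#' @export
print.methyl_cohort <- function(x, ...) {
  cat("<methyl_cohort>\n")
  cat(sprintf(
    "  %d features x %d samples; %d genes; clinical n=%d\n",
    nrow(x$counts), ncol(x$counts) - 1L, nrow(x$genes), nrow(x$clinical)
  ))
  invisible(x)
}

#' Simulate an MS-HRM melting curve
#'
#' The negative-derivative melting signal is a two-Gaussian mixture on a
#' temperature grid: an unmethylated-template peak at a lower melting
#' temperature and a methylated-template peak at a higher one, with peak
#' weights `(1 - true_fraction, true_fraction)`, plus additive Gaussian
#' noise.
#'
#' @param true_fraction Methylated fraction of the template, in `[0, 1]`.
#' @param noise_sd Additive Gaussian noise SD on the signal; must be
#'   non-negative.
#' @param seed Integer seed.
#' @param grid Ascending temperature grid in degrees Celsius.
#' @param unmeth_tm,meth_tm Peak centers (unmethylated < methylated).
#' @param peak_sd Common peak width (SD of each Gaussian component).
#' @param sample_id Optional label carried on the curve.
#' @return A tibble of class `melting_curve` with columns `temperature`
#'   and `signal`, plus peak parameters stored as attributes.
#' @export
simulate_melting_curve <- function(true_fraction, noise_sd = 0.01, seed = 1L,
                                   grid = seq(70, 95, by = 0.05),
                                   unmeth_tm = 78, meth_tm = 86,
                                   peak_sd = 1.2, sample_id = NULL) {
  if (!is.numeric(true_fraction) || length(true_fraction) != 1L ||
      is.na(true_fraction) || true_fraction < 0 || true_fraction > 1) {
    abort("`true_fraction` must be a single value in [0, 1].")
  }
  if (noise_sd < 0) abort("`noise_sd` must be non-negative.")
  if (is.unsorted(grid, strictly = TRUE)) {
    abort("`grid` must be strictly ascending.")
  }
  if (unmeth_tm >= meth_tm) abort("`unmeth_tm` must be below `meth_tm`.")
  with_seed(seed, {
    signal <- (1 - true_fraction) * dnorm(grid, unmeth_tm, peak_sd) +
      true_fraction * dnorm(grid, meth_tm, peak_sd)
    if (noise_sd > 0) signal <- signal + rnorm(length(grid), 0, noise_sd)
    out <- tibble::tibble(temperature = grid, signal = signal)
    attr(out, "unmeth_tm") <- unmeth_tm
    attr(out, "meth_tm") <- meth_tm
    attr(out, "peak_sd") <- peak_sd
    attr(out, "sample_id") <- sample_id
    class(out) <- c("melting_curve", class(out))
    out
  })
}

#' Simulate a two-group survival dataset
#'
#' Exponential event times with the hazard of the high-risk group
#' multiplied by `hazard_ratio`, and independent exponential censoring
#' tuned so that roughly `censoring_rate` of subjects are censored.
#'
#' @param groups Character/factor vector of group labels (exactly two
#'   distinct non-empty groups).
#' @param hazard_ratio Relative hazard of the high-risk group (> 0).
#' @param baseline_hazard Event rate of the reference group (> 0).
#' @param censoring_rate Expected censored fraction in `[0, 1)`; `0`
#'   yields fully observed data (`event` all 1).
#' @param seed Integer seed.
#' @param high_label Which label carries the elevated hazard; defaults to
#'   `"high_risk"` or `"high"` when present, otherwise the last sorted
#'   label.
#' @return A tibble with columns `subject_id`, `group`, `time`, `event`
#'   (1 = event observed, 0 = censored).
#' @export
simulate_survival <- function(groups, hazard_ratio, baseline_hazard = 0.05,
                              censoring_rate = 0.2, seed = 1L,
                              high_label = NULL) {
  groups <- as.character(groups)
  labs <- sort(unique(groups))
  if (length(labs) != 2L) {
    abort("`groups` must contain exactly two distinct labels.")
  }
  if (any(table(groups) == 0L)) abort("Both groups must be non-empty.")
  if (hazard_ratio <= 0) abort("`hazard_ratio` must be positive.")
  if (baseline_hazard <= 0) abort("`baseline_hazard` must be positive.")
  if (censoring_rate < 0 || censoring_rate >= 1) {
    abort("`censoring_rate` must lie in [0, 1).")
  }
  if (is.null(high_label)) {
    high_label <- if ("high_risk" %in% labs) {
      "high_risk"
    } else if ("high" %in% labs) {
      "high"
    } else {
      labs[[2L]]
    }
  }
  if (!high_label %in% labs) abort("`high_label` is not one of the group labels.")
  with_seed(seed, {
    n <- length(groups)
    rate <- baseline_hazard * ifelse(groups == high_label, hazard_ratio, 1)
    event_time <- rexp(n, rate)
    if (censoring_rate > 0) {
      cens_time <- rexp(n, rate * censoring_rate / (1 - censoring_rate))
      time <- pmin(event_time, cens_time)
      event <- as.integer(event_time <= cens_time)
    } else {
      time <- event_time
      event <- rep(1L, n)
    }
    tibble::tibble(
      subject_id = sprintf("s%04d", seq_len(n)),
      group = groups, time = time, event = event
    )
  })
}
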