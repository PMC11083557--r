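#' Configure an end-to-end pipeline run
#'
#' A single config drives the whole workflow: either a simulation block
#' ([sim_config()]) or paths to real input tables, plus every analysis
#' threshold. Defaults echo the study criteria: delta mean 0.2 on the 0-1
#' scale, p < 0.05, `|log2FC| >= log2(1.2)`.
#'
#' @param simulation A [sim_config()], or `NULL` when `inputs` is given.
#' @param inputs A named list of file paths (`counts`, `samples`,
#'   `genes`, `cgis`, `expression`, `clinical`, optionally `roi_info`
#'   with per-feature `length`/`cpg_count`), or `NULL` when simulating.
#' @param out_dir Output directory (created if needed).
#' @param delta_threshold,p_threshold,gate DMR-calling parameters, see
#'   [call_dmrs()].
#' @param fc_threshold_log2,expr_p_threshold Quadrant parameters, see
#'   [assign_quadrants()].
#' @param promoter_upstream,promoter_downstream,min_overlap_bp ROI
#'   parameters, see [build_rois()] and [classify_cgi()].
#' @param meth_margin,expr_margin Candidate-screen margins.
#' @param top_k Most-variable features kept for clustering (clamped to
#'   the feature count).
#' @param quantile_range,n_permutations Optimal-cutoff parameters.
#' @param target_subtype Subtype screened for specificity (default
#'   `"TNBC"`).
#' @param verbose Emit stage-by-stage progress messages.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = sim_config(), inputs = NULL,
                            out_dir = tempfile("methylquad_run_"),
                            delta_threshold = 0.2, p_threshold = 0.05,
                            gate = c("p", "q"),
                            fc_threshold_log2 = log2(1.2),
                            expr_p_threshold = 0.05,
                            promoter_upstream = 2000, promoter_downstream = 500,
                            min_overlap_bp = 1,
                            meth_margin = 0.1, expr_margin = 0.5,
                            top_k = 1000,
                            quantile_range = c(0.2, 0.8),
                            n_permutations = 200L,
                            target_subtype = "TNBC",
                            verbose = TRUE) {
  gate <- match.arg(gate)
  if (is.null(simulation) && is.null(inputs)) {
    abort("Provide either a `simulation` block or real `inputs`, not neither.")
  }
  if (!is.null(simulation) && !inherits(simulation, "sim_config")) {
    abort("`simulation` must be built with sim_config().")
  }
  if (delta_threshold < 0 || delta_threshold > 1) {
    abort("`delta_threshold` must lie in [0, 1].")
  }
  if (p_threshold <= 0 || p_threshold > 1) abort("`p_threshold` must lie in (0, 1].")
  if (fc_threshold_log2 < 0) abort("`fc_threshold_log2` must be non-negative.")
  if (length(quantile_range) != 2L || quantile_range[1L] >= quantile_range[2L] ||
      quantile_range[1L] < 0 || quantile_range[2L] > 1) {
    abort("`quantile_range` must be an increasing pair inside [0, 1].")
  }
  structure(
    list(
      simulation = simulation, inputs = inputs, out_dir = out_dir,
      delta_threshold = delta_threshold, p_threshold = p_threshold, gate = gate,
      fc_threshold_log2 = fc_threshold_log2, expr_p_threshold = expr_p_threshold,
      promoter_upstream = promoter_upstream,
      promoter_downstream = promoter_downstream,
      min_overlap_bp = min_overlap_bp,
      meth_margin = meth_margin, expr_margin = expr_margin,
      top_k = top_k, quantile_range = quantile_range,
      n_permutations = as.integer(n_permutations),
      target_subtype = target_subtype, verbose = verbose
    ),
    class = "pipeline_config"
  )
}

#' Read a pipeline config from YAML
#'
#' Top-level keys mirror the [pipeline_config()] arguments; a
#' `simulation:` mapping is passed to [sim_config()].
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$simulation)) {
    raw$simulation <- do.call(sim_config, raw$simulation)
  }
  do.call(pipeline_config, raw)
}

#' Run the full discovery pipeline
#'
#' Executes ROI annotation, methylation scoring, per-subtype differential
#' methylation, expression integration, candidate screening, and
#' composite-risk survival stratification in order, writing every output
#' table under `config$out_dir` and recording each file's MD5 checksum in
#' a manifest. A rerun with the same config (and simulation seed)
#' reproduces the checksums bit-exactly. A stage failure aborts with the
#' failing stage named; files already written are retained.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory results (`calls`,
#'   `composition`, `specificity`, `quadrants`, `candidates`,
#'   `survival`, `truth` when simulated, ...) and the `manifest` tibble
#'   (`file`, `md5`, `bytes`).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) {
    abort("`config` must be built with pipeline_config().")
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (isTRUE(config$verbose)) message(sprintf(...))
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  written <- character(0)
  emit <- function(x, file, writer) {
    path <- file.path(config$out_dir, file)
    writer(x, path)
    written <<- c(written, path)
    path
  }
  write_num_tsv <- function(x, path) {
    readr::write_tsv(dplyr::mutate(x, dplyr::across(
      dplyr::where(is.double), signif6
    )), path, progress = FALSE)
  }
  write_json_file <- function(x, path) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  ## ---- stage: inputs ---------------------------------------------------
  data <- run_stage("inputs", {
    if (!is.null(config$simulation)) {
      cohort <- simulate_cohort(config$simulation)
      inp_dir <- file.path(config$out_dir, "inputs")
      written <- c(written, write_cohort(cohort, inp_dir))
      say("inputs: simulated cohort with %d features x %d samples",
          nrow(cohort$counts), nrow(cohort$samples))
      list(
        counts = cohort$counts, samples = cohort$samples,
        genes = cohort$genes, cgis = cohort$cgis,
        expression = cohort$expression, clinical = cohort$clinical,
        library_sizes = cohort$library_sizes,
        rois = cohort$rois, truth = cohort$truth
      )
    } else {
      inp <- config$inputs
      counts <- readr::read_tsv(inp$counts, show_col_types = FALSE, progress = FALSE)
      samples <- readr::read_tsv(inp$samples, show_col_types = FALSE, progress = FALSE)
      lib <- colSums(feature_values(counts))
      roi_info <- if (!is.null(inp$roi_info)) {
        readr::read_tsv(inp$roi_info, show_col_types = FALSE, progress = FALSE)
      }
      list(
        counts = counts, samples = samples,
        genes = read_gene_models(inp$genes),
        cgis = read_cgi_bed(inp$cgis),
        expression = readr::read_tsv(inp$expression, show_col_types = FALSE, progress = FALSE),
        clinical = readr::read_tsv(inp$clinical, show_col_types = FALSE, progress = FALSE),
        library_sizes = lib, rois = NULL, roi_info = roi_info, truth = NULL
      )
    }
  })

  ## ---- stage: roi_annotation ------------------------------------------
  rois <- run_stage("roi_annotation", {
    if (!is.null(data$rois)) {
      data$rois
    } else {
      r <- classify_cgi(
        build_rois(data$genes, config$promoter_upstream, config$promoter_downstream),
        data$cgis, config$min_overlap_bp
      )
      r$feature_id <- paste(r$gene_id, r$region_class, sep = "|")
      r$length <- r$end - r$start
      if (!is.null(data$roi_info)) {
        r <- dplyr::left_join(r, data$roi_info, by = "feature_id")
      }
      r
    }
  })
  emit(rois, "rois.bed", write_rois_bed)
  say("roi_annotation: %d regions (%d CGI)", nrow(rois), sum(rois$cgi_class == "CGI"))

  ## ---- stage: methylome_scoring ---------------------------------------
  scaled <- run_stage("methylome_scoring", {
    key <- match(data$counts[[1L]], rois$feature_id)
    if (anyNA(key)) abort("Count features missing from the ROI table.")
    ams <- compute_ams(
      data$counts,
      roi_lengths = rois$length[key],
      library_sizes = data$library_sizes,
      cpg_counts = if ("cpg_count" %in% names(rois)) rois$cpg_count[key]
    )
    minmax_scale(ams)
  })
  emit(scaled, "methylation_scaled.tsv", write_num_tsv)

  ## ---- stage: differential_methylation --------------------------------
  subtypes <- unique(data$samples$subtype)
  diff_res <- run_stage("differential_methylation", {
    calls <- purrr::map(setNames(subtypes, subtypes), function(s) {
      call_dmrs(scaled, data$samples, s,
        delta_threshold = config$delta_threshold,
        p_threshold = config$p_threshold, gate = config$gate
      )
    })
    comp <- purrr::map(calls, context_composition, rois = rois)
    k <- min(config$top_k, nrow(scaled))
    topvar <- select_top_variable(scaled, k)
    hc <- average_linkage_cluster(scaled[match(topvar$feature_id, scaled[[1L]]), ])
    list(calls = calls, composition = comp, top_variable = topvar, tree = hc)
  })
  for (s in subtypes) {
    emit(diff_res$calls[[s]], sprintf("dmr_%s.tsv", s), write_num_tsv)
    emit(diff_res$composition[[s]], sprintf("composition_%s.json", s), write_json_file)
    n_hyper <- sum(diff_res$calls[[s]]$call == "hyper")
    n_hypo <- sum(diff_res$calls[[s]]$call == "hypo")
    say("differential_methylation [%s]: %d hyper / %d hypo", s, n_hyper, n_hypo)
  }
  emit(diff_res$top_variable, "top_variable.tsv", write_num_tsv)
  emit(diff_res$tree, "cluster.newick", function(x, path) {
    ape::write.tree(ape::as.phylo(x), file = path)
  })

  ## ---- stage: integration ---------------------------------------------
  integ <- run_stage("integration", {
    gene_sets <- function(direction) {
      purrr::map(diff_res$calls, function(cc) {
        unique(cc$gene_id[cc$call == direction])
      })
    }
    spec_hypo <- subtype_specific_sets(gene_sets("hypo"))
    spec_hyper <- subtype_specific_sets(gene_sets("hyper"))
    expr_diff <- expression_differential(
      data$expression, data$samples, config$target_subtype
    )
    collapsed <- collapse_gene_calls(diff_res$calls[[config$target_subtype]])
    quadrants <- assign_quadrants(collapsed, expr_diff,
      fc_threshold_log2 = config$fc_threshold_log2,
      expr_p_threshold = config$expr_p_threshold
    )
    tumor <- data$samples[data$samples$tumor_normal == "tumor", ]
    keep_cols <- c(names(scaled)[1L], tumor$sample)
    candidates <- candidate_screen(
      quadrants,
      meth = scaled[, keep_cols],
      expr = data$expression[, c(names(data$expression)[1L], tumor$sample)],
      sample_subtypes = setNames(tumor$subtype, tumor$sample),
      target_subtype = config$target_subtype,
      meth_margin = config$meth_margin, expr_margin = config$expr_margin
    )
    list(
      specificity = list(hypo = spec_hypo, hyper = spec_hyper),
      expr_diff = expr_diff, quadrants = quadrants, candidates = candidates
    )
  })
  emit(integ$expr_diff, "expression_differential.tsv", write_num_tsv)
  emit(integ$quadrants, "quadrants.tsv", write_num_tsv)
  emit(
    list(
      hypo = c(integ$specificity$hypo["specific"], integ$specificity$hypo["shared"]),
      hyper = c(integ$specificity$hyper["specific"], integ$specificity$hyper["shared"])
    ),
    "specificity.json", write_json_file
  )
  emit(integ$candidates, "candidates.tsv", write_num_tsv)
  say(
    "integration: %d quadrant genes, %d passing candidates",
    sum(integ$quadrants$quadrant != "none"), sum(integ$candidates$passes)
  )

  ## ---- stage: survival_analysis ---------------------------------------
  surv <- run_stage("survival_analysis", {
    clin <- data$clinical
    rule <- if (!is.null(data$truth) && !is.null(data$truth$marker)) {
      data$truth$marker$rule
    } else {
      risk_rule("marker", "hypo", "high")
    }
    meth_lab <- median_split(clin$marker_methylation)
    expr_lab <- median_split(clin$marker_expression)
    risk <- composite_risk(meth_lab, expr_lab, rule)
    rec <- tibble::tibble(time = clin$time, event = clin$event, group = risk)
    lr <- logrank_test(rec)
    km <- purrr::map(
      setNames(unique(risk), unique(risk)),
      function(g) km_estimate(rec[rec$group == g, ])
    )
    cut <- optimal_cutoff(
      clin$marker_expression, clin,
      quantile_range = config$quantile_range,
      n_permutations = config$n_permutations
    )
    list(rule = rule, risk = risk, logrank = lr, km = km, cutoff = cut)
  })
  km_tbl <- dplyr::bind_rows(
    purrr::imap(surv$km, ~ dplyr::mutate(tidy(.x), group = .y, .before = 1L))
  )
  emit(km_tbl, "km_curves.tsv", write_num_tsv)
  emit(
    list(
      rule = unclass(surv$rule),
      n_high_risk = sum(surv$risk == "high_risk"),
      n_low_risk = sum(surv$risk == "low_risk"),
      logrank = list(
        statistic = surv$logrank$statistic,
        p_value = surv$logrank$p_value, df = surv$logrank$df
      ),
      optimal_cutoff = list(
        cutoff = surv$cutoff$cutoff,
        p_uncorrected = surv$cutoff$p_uncorrected,
        p_adjusted = surv$cutoff$p_adjusted
      )
    ),
    "survival_report.json", write_json_file
  )
  say(
    "survival_analysis: log-rank p = %.4g (high risk n=%d)",
    surv$logrank$p_value, sum(surv$risk == "high_risk")
  )

  ## ---- manifest --------------------------------------------------------
  manifest <- tibble::tibble(
    file = sub(paste0("^", config$out_dir, "/?"), "", written),
    md5 = unname(tools::md5sum(written)),
    bytes = file.size(written)
  )
  readr::write_tsv(manifest, file.path(config$out_dir, "manifest.tsv"), progress = FALSE)

  invisible(list(
    rois = rois, scaled = scaled,
    calls = diff_res$calls, composition = diff_res$composition,
    top_variable = diff_res$top_variable, tree = diff_res$tree,
    specificity = integ$specificity, expr_diff = integ$expr_diff,
    quadrants = integ$quadrants, candidates = integ$candidates,
    survival = surv, truth = data$truth, manifest = manifest,
    config = config
  ))
}

#' Write a simulated cohort to disk in the pipeline's input dialects
#'
#' Counts, expression, sample metadata and clinical tables as TSV, the
#' CpG-island track as 3-column BED, ROI annotation as BED6 plus a
#' per-feature info TSV, and the planted truth as a JSON sidecar.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return The written file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    counts = file.path(dir, "counts.tsv"),
    samples = file.path(dir, "samples.tsv"),
    genes = file.path(dir, "genes.tsv"),
    cgis = file.path(dir, "cgis.bed"),
    rois = file.path(dir, "rois.bed"),
    roi_info = file.path(dir, "roi_info.tsv"),
    expression = file.path(dir, "expression.tsv"),
    clinical = file.path(dir, "clinical.tsv"),
    library_sizes = file.path(dir, "library_sizes.tsv"),
    truth = file.path(dir, "truth.json")
  )
  num6 <- function(x) dplyr::mutate(x, dplyr::across(dplyr::where(is.double), signif6))
  readr::write_tsv(cohort$counts, paths[["counts"]], progress = FALSE)
  readr::write_tsv(cohort$samples, paths[["samples"]], progress = FALSE)
  readr::write_tsv(cohort$genes, paths[["genes"]], progress = FALSE)
  readr::write_tsv(cohort$cgis, paths[["cgis"]], col_names = FALSE, progress = FALSE)
  write_rois_bed(cohort$rois, paths[["rois"]])
  readr::write_tsv(
    cohort$rois[, c("feature_id", "length", "cpg_count")],
    paths[["roi_info"]], progress = FALSE
  )
  readr::write_tsv(num6(cohort$expression), paths[["expression"]], progress = FALSE)
  readr::write_tsv(num6(cohort$clinical), paths[["clinical"]], progress = FALSE)
  readr::write_tsv(
    tibble::tibble(
      sample = names(cohort$library_sizes),
      library_size = unname(cohort$library_sizes)
    ),
    paths[["library_sizes"]], progress = FALSE
  )
  truth <- cohort$truth
  jsonlite::write_json(
    list(
      specific_hyper = truth$specific_hyper,
      specific_hypo = truth$specific_hypo,
      shared = truth$shared,
      planted = truth$planted,
      marker = if (!is.null(truth$marker)) {
        list(
          gene_id = truth$marker$gene_id,
          rule = unclass(truth$marker$rule),
          subtype = truth$marker$subtype
        )
      },
      target_subtype = truth$target_subtype
    ),
    paths[["truth"]], auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(unname(paths))
}
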