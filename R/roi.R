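#' Build promoter and CDS regions of interest per gene
#'
#' For each gene model, emits one promoter ROI — `[tss - upstream,
#' tss + downstream)` on the plus strand, mirrored on the minus strand —
#' and one CDS ROI spanning the annotated CDS. All coordinates are
#' 0-based half-open (BED convention) and are clipped at 0 with a warning
#' when a promoter window runs off the chromosome start.
#'
#' @param genes A data frame with columns `gene_id`, `chrom`, `strand`
#'   (`"+"`/`"-"`), `tss`, `cds_start`, `cds_end` (0-based half-open).
#' @param promoter_upstream,promoter_downstream Promoter window sizes in
#'   bp relative to the TSS, both positive.
#' @return A tibble of ROI records: `gene_id`, `chrom`, `strand`,
#'   `start`, `end`, `region_class` (`"promoter"`/`"CDS"`), `cgi_class`
#'   (`NA` until [classify_cgi()] is applied).
#' @examples
#' g <- tibble::tibble(gene_id = "g1", chrom = "chr1", strand = "+",
#'                     tss = 10000L, cds_start = 10200L, cds_end = 12000L)
#' build_rois(g)
#' @export
build_rois <- function(genes, promoter_upstream = 2000, promoter_downstream = 500) {
  needed <- c("gene_id", "chrom", "strand", "tss", "cds_start", "cds_end")
  if (!is.data.frame(genes) || !all(needed %in% names(genes))) {
    abort(paste0(
      "`genes` must contain columns ",
      paste(needed, collapse = ", "), "."
    ))
  }
  if (promoter_upstream <= 0 || promoter_downstream <= 0) {
    abort("Promoter window sizes must be positive.")
  }
  if (!all(genes$strand %in% c("+", "-"))) {
    abort("`strand` must be '+' or '-'.")
  }
  if (any(genes$cds_start >= genes$cds_end)) {
    abort("Every gene must satisfy cds_start < cds_end.")
  }

  plus <- genes$strand == "+"
  prom_start <- ifelse(plus, genes$tss - promoter_upstream,
    genes$tss - promoter_downstream
  )
  prom_end <- ifelse(plus, genes$tss + promoter_downstream,
    genes$tss + promoter_upstream
  )
  if (any(prom_start < 0)) {
    warn(sprintf(
      "%d promoter window(s) extended past the chromosome start and were clipped at 0.",
      sum(prom_start < 0)
    ))
    prom_start <- pmax(prom_start, 0)
  }

  out <- dplyr::bind_rows(
    tibble::tibble(
      gene_id = genes$gene_id, chrom = genes$chrom, strand = genes$strand,
      start = as.integer(prom_start), end = as.integer(prom_end),
      region_class = "promoter"
    ),
    tibble::tibble(
      gene_id = genes$gene_id, chrom = genes$chrom, strand = genes$strand,
      start = as.integer(genes$cds_start), end = as.integer(genes$cds_end),
      region_class = "CDS"
    )
  )
  out$cgi_class <- NA_character_
  dplyr::arrange(out, .data$gene_id, dplyr::desc(.data$region_class == "promoter"))
}

#' Classify regions of interest by CpG-island overlap
#'
#' An ROI is labeled `CGI` when its overlap with any CpG-island interval
#' reaches `min_overlap_bp` (half-open intervals: a shared endpoint is no
#' overlap), otherwise `nonCGI`. Chromosomes present in the ROIs but
#' missing from the island track are labeled `nonCGI` with a warning.
#' Input row order is preserved.
#'
#' @param rois ROI records as produced by [build_rois()].
#' @param cgis CpG-island intervals: a data frame with columns `chrom`,
#'   `start`, `end` (0-based half-open, BED-style).
#' @param min_overlap_bp Minimum overlap in bp to count as CGI (default 1).
#' @return `rois` with `cgi_class` filled in.
#' @export
classify_cgi <- function(rois, cgis, min_overlap_bp = 1) {
  if (!is.data.frame(rois) || !all(c("chrom", "start", "end") %in% names(rois))) {
    abort("`rois` must contain columns chrom, start, end.")
  }
  if (!is.data.frame(cgis) || !all(c("chrom", "start", "end") %in% names(cgis))) {
    abort("`cgis` must contain columns chrom, start, end.")
  }
  if (min_overlap_bp < 1) abort("`min_overlap_bp` must be at least 1.")
  if (any(rois$start >= rois$end)) abort("ROIs must satisfy start < end.")

  missing_chrom <- setdiff(unique(rois$chrom), unique(cgis$chrom))
  if (length(missing_chrom) && nrow(rois)) {
    warn(sprintf(
      "No CpG islands on chromosome(s) %s; their ROIs are labeled nonCGI.",
      paste(missing_chrom, collapse = ", ")
    ))
  }

  rois$cgi_class <- "nonCGI"
  if (nrow(cgis) && nrow(rois)) {
    # 0-based half-open -> 1-based closed for IRanges
    q <- GenomicRanges::GRanges(
      rois$chrom, IRanges::IRanges(rois$start + 1L, rois$end)
    )
    s <- GenomicRanges::GRanges(
      cgis$chrom, IRanges::IRanges(cgis$start + 1L, cgis$end)
    )
    # suppress seqlevel-mismatch chatter; missing chromosomes warned above
    hits <- suppressWarnings(
      GenomicRanges::findOverlaps(q, s, minoverlap = as.integer(min_overlap_bp))
    )
    rois$cgi_class[unique(S4Vectors::queryHits(hits))] <- "CGI"
  }
  rois
}

#' Read gene models from a TSV file
#'
#' Expects at least the six columns `gene_id`, `chrom`, `strand`, `tss`,
#' `cds_start`, `cds_end`. Coordinates are interpreted as 0-based
#' half-open unless `one_based = TRUE`, in which case starts and the TSS
#' are shifted down by one.
#'
#' @param path TSV file path.
#' @param one_based Set when the file uses 1-based inclusive coordinates.
#' @return A tibble of gene models.
#' @export
read_gene_models <- function(path, one_based = FALSE) {
  genes <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("gene_id", "chrom", "strand", "tss", "cds_start", "cds_end")
  if (!all(needed %in% names(genes))) {
    abort(paste0("Gene model file must contain columns ", paste(needed, collapse = ", "), "."))
  }
  if (one_based) {
    genes$tss <- genes$tss - 1L
    genes$cds_start <- genes$cds_start - 1L
  }
  genes
}

#' Read CpG islands from a 3-column BED file
#' @param path BED file path (chrom, start, end; no header).
#' @return A tibble with columns `chrom`, `start`, `end`.
#' @export
read_cgi_bed <- function(path) {
  readr::read_tsv(path,
    col_names = c("chrom", "start", "end"),
    col_types = "cii", progress = FALSE
  )
}

#' Write ROIs as BED6
#'
#' The name field encodes `gene|region_class|cgi_class`; the score field
#' is 0 and the strand column is taken from the records.
#'
#' @param rois Classified ROI records.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rois_bed <- function(rois, path) {
  bed <- tibble::tibble(
    chrom = rois$chrom,
    start = rois$start,
    end = rois$end,
    name = paste(rois$gene_id, rois$region_class, rois$cgi_class, sep = "|"),
    score = 0L,
    strand = if ("strand" %in% names(rois)) rois$strand else "."
  )
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
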