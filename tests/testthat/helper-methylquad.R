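# Shared fixtures and independent brute-force oracles.

# A small paired two-subtype score matrix with hand-set effects.
toy_samples <- function(n_pairs = 4, subtypes = c("TNBC", "LumA")) {
  out <- expand.grid(
    tumor_normal = c("tumor", "normal"),
    pair = seq_len(n_pairs),
    subtype = subtypes,
    stringsAsFactors = FALSE
  )
  out$pair_id <- sprintf("%s_p%d", out$subtype, out$pair)
  out$sample <- sprintf(
    "%s_%s%d", out$subtype,
    ifelse(out$tumor_normal == "tumor", "T", "N"), out$pair
  )
  tibble::as_tibble(out[, c("sample", "subtype", "tumor_normal", "pair_id")])
}

# Brute-force step-up BH straight from the definition.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  sp <- p[o]
  q_sorted <- vapply(seq_len(m), function(i) {
    min(sp[i:m] * m / (i:m), 1)
  }, numeric(1L))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Brute-force UPGMA: recompute the mean of all cross-pair *original*
# distances at every step (no linkage-update recursion). Returns the
# leaf set and height of each merge; with continuous data ties are
# measure-zero so merge order is well defined.
upgma_oracle <- function(points) {
  d <- as.matrix(dist(points))
  clusters <- as.list(seq_len(nrow(d)))
  merges <- list()
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    k <- length(clusters)
    best <- NULL
    best_d <- Inf
    for (i in seq_len(k - 1L)) {
      for (j in seq(i + 1L, k)) {
        dd <- mean(d[clusters[[i]], clusters[[j]]])
        if (dd < best_d) {
          best_d <- dd
          best <- c(i, j)
        }
      }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    merges <- c(merges, list(merged))
    heights <- c(heights, best_d)
    clusters <- c(clusters[-best], list(merged))
  }
  list(merges = merges, heights = heights)
}

# Leaf sets per merge from an hclust object, for comparison with the oracle.
hclust_merge_sets <- function(hc) {
  sets <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    members <- function(code) if (code < 0) -code else sets[[code]]
    sets[[i]] <- sort(c(members(hc$merge[i, 1]), members(hc$merge[i, 2])))
  }
  sets
}

# All-pairs interval-overlap scan (0-based half-open).
cgi_overlap_oracle <- function(rois, cgis, min_overlap_bp = 1) {
  vapply(seq_len(nrow(rois)), function(i) {
    same <- cgis[cgis$chrom == rois$chrom[i], , drop = FALSE]
    if (!nrow(same)) return("nonCGI")
    ov <- pmin(rois$end[i], same$end) - pmax(rois$start[i], same$start)
    if (any(ov >= min_overlap_bp)) "CGI" else "nonCGI"
  }, character(1L))
}

# Membership-count specificity oracle: specific iff a gene appears in
# exactly one subtype's set, shared iff it appears in all of them.
specificity_oracle <- function(call_sets) {
  all_genes <- unique(unlist(call_sets))
  counts <- vapply(all_genes, function(g) {
    sum(vapply(call_sets, function(s) g %in% s, logical(1L)))
  }, integer(1L))
  specific <- lapply(call_sets, function(s) {
    s[s %in% all_genes[counts == 1L]]
  })
  list(
    specific = specific,
    shared = sort(all_genes[counts == length(call_sets)])
  )
}

# Random small survival dataset for oracle comparisons.
random_survival <- function(n) {
  tibble::tibble(
    time = round(rexp(n, 0.1), 3),
    event = rbinom(n, 1, 0.7),
    group = sample(c("A", "B"), n, replace = TRUE)
  )
}
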