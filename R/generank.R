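## ---------------------------------------------------------------------------
## Gene-locus cross-disease prioritization: best-nearby-SNP gene scores,
## geometric-mean rank aggregation, and permutation gene-set tests.
## ---------------------------------------------------------------------------

#' Build gene loci from TSS annotations
#'
#' Each locus is a symmetric window around the TSS; capture-linked regions,
#' when provided, extend (union, not replace) the candidate SNP pool.
#'
#' @param genes Data frame with `gene`, `chrom`, `tss` (0-based), optional
#'   `strand`.
#' @param window Half-width of the locus window in bp (default 1e5).
#' @param linked Optional data frame of linked regions: `gene`, `chrom`,
#'   `start`, `end` (0-based half-open), e.g. filtered promoter-capture pairs.
#' @return Named list (by gene) of `GRanges` candidate windows.
#' @export
gene_loci <- function(genes, window = 1e5, linked = NULL) {
  loci <- lapply(seq_len(nrow(genes)), function(i) {
    GenomicRanges::GRanges(genes$chrom[i],
                           IRanges::IRanges(pmax(1, genes$tss[i] - window + 1),
                                            genes$tss[i] + window))
  })
  names(loci) <- genes$gene
  if (!is.null(linked) && nrow(linked)) {
    for (g in intersect(unique(linked$gene), names(loci))) {
      lk <- linked[linked$gene == g, , drop = FALSE]
      loci[[g]] <- GenomicRanges::reduce(suppressWarnings(c(
        loci[[g]],
        GenomicRanges::GRanges(lk$chrom,
                               IRanges::IRanges(lk$start + 1L, lk$end)))))
    }
  }
  loci
}

#' Per-disease per-gene best nearby SNP score
#'
#' A gene's score for a disease is the minimum p-value over SNPs inside its
#' locus windows. An optional region-set filter restricts the candidate SNPs
#' to those near the filter set first (this is how region-class-conditioned
#' rankings are produced). Genes with no candidate SNP for a disease score
#' `NA` and are flagged.
#'
#' @param panel Named list of per-disease data frames (`variant`, `p`) or a
#'   p-value matrix (variants x diseases).
#' @param variants Data frame of the variant universe: `variant`, `chrom`,
#'   `pos` (0-based).
#' @param loci Named list of `GRanges` from [gene_loci()].
#' @param filter Optional `GRanges`; only SNPs within `filter_window` of it
#'   are eligible.
#' @param filter_window Proximity window for the filter (default 10000).
#' @return List with `scores` (genes x diseases matrix of best p) and
#'   `no_data` (logical matrix of the same shape).
#' @export
gene_scores <- function(panel, variants, loci, filter = NULL,
                        filter_window = 10000) {
  if (is.matrix(panel) || is.data.frame(panel)) {
    pm <- as.matrix(panel)
    panel <- lapply(stats::setNames(seq_len(ncol(pm)), colnames(pm)),
                    function(j) data.frame(variant = rownames(pm),
                                           p = pm[, j]))
  }
  if (!length(panel)) stop("empty panel")
  v <- variants
  if (!is.null(filter)) {
    keep <- near_region_flags(v$chrom, v$pos, filter, window = filter_window)
    v <- v[keep, , drop = FALSE]
  }
  pts <- GenomicRanges::GRanges(v$chrom, IRanges::IRanges(v$pos + 1, v$pos + 1))
  # gene -> candidate variant ids
  cand <- lapply(loci, function(gr) {
    v$variant[suppressWarnings(
      IRanges::overlapsAny(pts, gr, ignore.strand = TRUE))]
  })
  genes <- names(loci)
  scores <- matrix(NA_real_, length(genes), length(panel),
                   dimnames = list(genes, names(panel)))
  for (ds in names(panel)) {
    d <- panel[[ds]]
    pv <- stats::setNames(d$p, d$variant)
    for (g in genes) {
      pp <- pv[cand[[g]]]
      pp <- pp[!is.na(pp)]
      if (length(pp)) scores[g, ds] <- min(pp)
    }
  }
  list(scores = scores, no_data = is.na(scores))
}

#' Aggregate per-disease gene scores into cross-disease ranks
#'
#' Within each disease, genes are ranked ascending by p (rank 1 = strongest),
#' ties by average rank; genes with no data are placed after all ranked genes
#' at `n_ranked + (n_nodata + 1) / 2`. The aggregate is the geometric mean of
#' per-disease ranks, so it is invariant to any monotone transform of the
#' per-disease scores.
#'
#' @param scores Genes x diseases matrix of best p-values (`NA` = no data).
#' @return Data frame sorted by aggregate: `gene`, `aggregate`,
#'   `n_no_data`, plus the per-disease rank matrix in attribute `ranks`.
#' @export
aggregate_ranks <- function(scores) {
  scores <- as.matrix(scores)
  if (ncol(scores) < 2) stop("need >= 2 diseases")
  if (all(is.na(scores))) stop("all genes have no data")
  ranks <- apply(scores, 2, function(s) {
    r <- rank(s, ties.method = "average", na.last = "keep")
    n_ranked <- sum(!is.na(s))
    n_na <- sum(is.na(s))
    r[is.na(s)] <- n_ranked + (n_na + 1) / 2
    r
  })
  agg <- exp(rowMeans(log(ranks)))
  out <- data.frame(gene = rownames(scores),
                    aggregate = agg,
                    n_no_data = rowSums(is.na(scores)),
                    stringsAsFactors = FALSE)
  out <- out[order(out$aggregate), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "ranks") <- ranks
  out
}

#' Permutation test of a gene set's cross-disease ranking
#'
#' Statistic: mean aggregate rank of the set. Null: the same statistic over
#' `n_perm` uniform draws of equal-size gene sets from the universe.
#' Empirical p = `(1 + #{null <= observed}) / (n_perm + 1)` (small = the set
#' ranks better than random).
#'
#' @param rank_table Data frame from [aggregate_ranks()].
#' @param gene_set Character vector of gene ids (subset of the universe).
#' @param n_perm Number of random sets (default 999).
#' @param seed Optional seed.
#' @return List with `observed`, `null_mean`, `p`, `n_set`, `n_perm`.
#' @export
gene_set_test <- function(rank_table, gene_set, n_perm = 999, seed = NULL) {
  universe <- rank_table$gene
  gene_set <- unique(gene_set)
  if (!all(gene_set %in% universe)) stop("gene set not within universe")
  if (length(gene_set) > length(universe)) stop("set larger than universe")
  if (!is.null(seed)) set.seed(seed)
  agg <- stats::setNames(rank_table$aggregate, rank_table$gene)
  obs <- mean(agg[gene_set])
  k <- length(gene_set)
  null <- replicate(n_perm, mean(agg[sample(universe, k)]))
  list(observed = obs, null_mean = mean(null),
       p = (1 + sum(null <= obs)) / (n_perm + 1),
       n_set = k, n_perm = n_perm)
}
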