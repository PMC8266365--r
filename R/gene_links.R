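## ---------------------------------------------------------------------------
## Region-to-gene linking: promoter-capture filtering, the three linking
## rules (capture / promoter window / regulatory domain), and gene-set
## overlap tests.
## ---------------------------------------------------------------------------

#' Filter promoter-capture pairs by tissue reproducibility
#'
#' Keeps a (region, gene) interaction only when observed in at least
#' `min_tissues` distinct tissues/cell types, excluding one-dataset-exclusive
#' contacts. Idempotent.
#'
#' @param pairs Data frame with `chrom`, `start`, `end` (0-based half-open),
#'   `gene`, `tissue` — one row per (region, gene, tissue) record.
#' @param min_tissues Minimum distinct tissues (default 2).
#' @return Data frame of unique reproducible pairs: `chrom`, `start`, `end`,
#'   `gene`, `n_tissues`.
#' @export
filter_capture <- function(pairs, min_tissues = 2L) {
  if (!nrow(pairs)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), gene = character(),
                      n_tissues = integer()))
  }
  key <- paste(pairs$chrom, pairs$start, pairs$end, pairs$gene, sep = "\r")
  nt <- tapply(pairs$tissue, key, function(x) length(unique(x)))
  keep <- names(nt)[nt >= min_tissues]
  uq <- !duplicated(key) & key %in% keep
  out <- pairs[uq, c("chrom", "start", "end", "gene"), drop = FALSE]
  out$n_tissues <- as.integer(nt[paste(out$chrom, out$start, out$end,
                                       out$gene, sep = "\r")])
  rownames(out) <- NULL
  out
}

#' Link a region set to genes
#'
#' A gene is linked when any of the three rules fires (union): (1) a filtered
#' capture pair whose region overlaps the set; (2) the set overlaps the
#' gene's promoter window; (3) the set overlaps the gene's regulatory-domain
#' annotation. `rules` restricts which rules apply.
#'
#' @param regions `GRanges` region set.
#' @param capture Filtered capture pairs from [filter_capture()] (or `NULL`).
#' @param promoters `GRanges` with a `gene` column (see
#'   [promoter_windows()]); or `NULL`.
#' @param domains Optional `GRanges` with a `gene` column (pre-computed
#'   regulatory-domain annotations).
#' @param rules Subset of `c("capture", "promoter", "domain")`.
#' @return Character vector of linked gene ids (sorted, unique).
#' @export
regions_to_genes <- function(regions, capture = NULL, promoters = NULL,
                             domains = NULL,
                             rules = c("capture", "promoter", "domain")) {
  genes <- character()
  if ("capture" %in% rules && !is.null(capture) && nrow(capture)) {
    cg <- GenomicRanges::GRanges(capture$chrom,
                                 IRanges::IRanges(capture$start + 1L,
                                                  capture$end))
    hit <- suppressWarnings(
      IRanges::overlapsAny(cg, regions, ignore.strand = TRUE))
    genes <- c(genes, capture$gene[hit])
  }
  if ("promoter" %in% rules && !is.null(promoters) && length(promoters)) {
    hit <- suppressWarnings(
      IRanges::overlapsAny(promoters, regions, ignore.strand = TRUE))
    genes <- c(genes, S4Vectors::mcols(promoters)$gene[hit])
  }
  if ("domain" %in% rules && !is.null(domains) && length(domains)) {
    hit <- suppressWarnings(
      IRanges::overlapsAny(domains, regions, ignore.strand = TRUE))
    genes <- c(genes, S4Vectors::mcols(domains)$gene[hit])
  }
  sort(unique(genes))
}

#' Hypergeometric overlap test of two gene sets
#'
#' One-sided enrichment p for the observed overlap given both sets are drawn
#' from the universe, exact.
#'
#' @param set_a,set_b Character vectors of gene ids.
#' @param universe Character vector containing both sets.
#' @return List with `overlap`, `n_a`, `n_b`, `n_universe`, `p`.
#' @export
set_overlap_test <- function(set_a, set_b, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  set_a <- unique(intersect(set_a, universe))
  set_b <- unique(intersect(set_b, universe))
  k <- length(intersect(set_a, set_b))
  N <- length(universe)
  p <- stats::phyper(k - 1, length(set_a), N - length(set_a),
                     length(set_b), lower.tail = FALSE)
  list(overlap = k, n_a = length(set_a), n_b = length(set_b),
       n_universe = N, p = p)
}
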