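## ---------------------------------------------------------------------------
## Cross-tissue gene-expression shift calling: fetal/adult consistency score
## and the young/old moderated contrast (shared engine with accessibility).
## ---------------------------------------------------------------------------

#' Filter lowly-expressed genes
#'
#' Keeps genes with at least `min_cpm` counts-per-million in at least
#' `min_frac` of samples.
#'
#' @param counts Genes x samples count matrix.
#' @param min_cpm CPM threshold (default 1).
#' @param min_frac Fraction of samples (default 0.5).
#' @return List with `counts` (filtered), `kept` (logical), `n_removed`.
#' @export
filter_expressed <- function(counts, min_cpm = 1, min_frac = 0.5) {
  counts <- as.matrix(counts)
  lib <- colSums(counts)
  cpm <- t(t(counts) / lib * 1e6)
  kept <- rowMeans(cpm >= min_cpm) >= min_frac
  list(counts = counts[kept, , drop = FALSE], kept = kept,
       n_removed = sum(!kept))
}

#' Cross-tissue consistency calling of stage-biased expression
#'
#' A deliberately less stringent caller for broad fetal-to-adult expression
#' change: per tissue, the adult-vs-fetal log2 fold-change is the difference
#' of replicate-mean log2-CPM; a gene is called adult-up when its fold-change
#' is at least `min_logfc` in at least `min_tissues` tissues and at most
#' `-min_logfc` in none (the veto excludes antagonistic genes); fetal-up is
#' symmetric.
#'
#' @param counts Genes x samples count matrix.
#' @param meta Sample sheet with `sample_id`, `tissue`, `stage`.
#' @param min_tissues Minimum consistent tissues (default: majority,
#'   `ceiling(n_tissues / 2)`).
#' @param min_logfc Log2 fold-change magnitude threshold (default 1).
#' @param min_cpm,min_frac Expression filter (see [filter_expressed()]).
#' @return List with `adult_up`, `fetal_up` (gene id vectors), `logfc`
#'   (genes x tissues matrix), `n_low_expressed`.
#' @export
consistency_shift <- function(counts, meta, min_tissues = NULL,
                              min_logfc = 1, min_cpm = 1, min_frac = 0.5) {
  tis <- unique(meta$tissue)
  both <- vapply(tis, function(t) {
    all(c("fetal", "adult") %in% meta$stage[meta$tissue == t])
  }, logical(1))
  tis <- tis[both]
  if (length(tis) < 2) stop("need >= 2 tissues with both stages")
  if (is.null(min_tissues)) min_tissues <- ceiling(length(tis) / 2)
  fl <- filter_expressed(counts, min_cpm, min_frac)
  lc <- normalize_counts(fl$counts)$logcpm
  lfc <- sapply(tis, function(t) {
    ad <- meta$sample_id[meta$tissue == t & meta$stage == "adult"]
    fe <- meta$sample_id[meta$tissue == t & meta$stage == "fetal"]
    rowMeans(lc[, ad, drop = FALSE]) - rowMeans(lc[, fe, drop = FALSE])
  })
  up_ok <- rowSums(lfc >= min_logfc) >= min_tissues &
    rowSums(lfc <= -min_logfc) == 0
  dn_ok <- rowSums(lfc <= -min_logfc) >= min_tissues &
    rowSums(lfc >= min_logfc) == 0
  list(adult_up = rownames(lfc)[up_ok],
       fetal_up = rownames(lfc)[dn_ok],
       logfc = lfc,
       n_low_expressed = fl$n_removed)
}

#' Young/old differential expression in adults
#'
#' Runs the shared moderated engine on adult expression counts with
#' precision weights, splitting samples at `age_split` years — the same
#' machinery and age definitions as the accessibility contrast.
#'
#' @param counts Genes x samples count matrix (all samples; adults used).
#' @param meta Sample sheet with `stage`, `tissue`, `age`.
#' @param age_split Years (default 50).
#' @param weights Use precision weights (default `TRUE`).
#' @param min_cpm,min_frac Expression filter.
#' @return Data frame from [moderated_fit()] over the filtered genes.
#' @export
age_expression_contrast <- function(counts, meta, age_split = 50,
                                    weights = TRUE, min_cpm = 1,
                                    min_frac = 0.5) {
  adult <- meta$stage == "adult"
  if (!any(adult)) stop("no adult samples")
  ma <- meta[adult, , drop = FALSE]
  if (any(is.na(ma$age))) stop("adult samples missing ages")
  ma$age_group <- factor(ifelse(ma$age < age_split, "young", "old"),
                         levels = c("young", "old"))
  if (length(unique(ma$age_group)) < 2) stop("one age group empty")
  fl <- filter_expressed(as.matrix(counts)[, adult, drop = FALSE],
                         min_cpm, min_frac)
  des <- if (length(unique(ma$tissue)) > 1) {
    stats::model.matrix(~ age_group + factor(tissue), data = ma)
  } else {
    stats::model.matrix(~ age_group, data = ma)
  }
  nc <- normalize_counts(fl$counts, design = des, weights = weights)
  moderated_fit(nc$logcpm, des, coef = 2, weights = nc$weights)
}
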