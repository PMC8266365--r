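## ---------------------------------------------------------------------------
## Cross-disease per-SNP aggregation and per-disease enrichment of strong
## GWAS variants near region sets.
## ---------------------------------------------------------------------------

#' Cross-disease (cross-set) per-variant association metric
#'
#' Converts each per-disease two-sided p-value into unsigned evidence
#' `z_i = qnorm(1 - p_i/2)` (the magnitude of the corresponding z-score) and
#' standardizes the Stouffer-style sum so that under the global null the
#' metric has mean 0 and standard deviation 1:
#' `z_cross = (sum(z_i) - n * E0) / (sqrt(n) * SD0)`, with `E0 = sqrt(2/pi)`
#' and `SD0 = sqrt(1 - 2/pi)` the moments of `|N(0,1)|`. Disease effect signs
#' are incommensurable across traits, hence the unsigned default; a mean
#' `-log10(p)` alternative is available via `method`.
#'
#' @param pmat Numeric matrix of p-values, variants x diseases (`NA` = variant
#'   not tested for that disease; dropped from the sum with `n` adjusted).
#' @param min_diseases Minimum diseases observed for a variant to be scored
#'   (default: all diseases present in `pmat`).
#' @param method `"abs_z"` (default) or `"mean_log10p"`.
#' @return Data frame with `variant`, `z_cross`, `n_diseases_observed`
#'   (`z_cross` is `NA` below `min_diseases`).
#' @export
cross_set_metric <- function(pmat, min_diseases = ncol(pmat),
                             method = c("abs_z", "mean_log10p")) {
  method <- match.arg(method)
  pmat <- as.matrix(pmat)
  if (!length(pmat)) stop("empty panel")
  if (any(pmat <= 0, na.rm = TRUE)) {
    warning("p-values of 0 clamped to smallest representable positive value")
    pmat[pmat <= 0] <- .Machine$double.xmin
  }
  if (any(pmat > 1, na.rm = TRUE)) stop("p-values above 1")
  nobs <- rowSums(!is.na(pmat))
  if (method == "abs_z") {
    z <- stats::qnorm(1 - pmat / 2)
    e0 <- sqrt(2 / pi)
    sd0 <- sqrt(1 - 2 / pi)
    zc <- (rowSums(z, na.rm = TRUE) - nobs * e0) / (sqrt(nobs) * sd0)
  } else {
    zc <- rowMeans(-log10(pmat), na.rm = TRUE)
  }
  zc[nobs < min_diseases] <- NA_real_
  data.frame(variant = if (!is.null(rownames(pmat))) rownames(pmat)
             else paste0("v", seq_len(nrow(pmat))),
             z_cross = zc,
             n_diseases_observed = nobs,
             stringsAsFactors = FALSE)
}

#' Exact hypergeometric tails of a 2x2 enrichment table
#'
#' Upper tail `P(X >= k)` and lower tail `P(X <= k)` for `k` successes among
#' `n_draw` draws from `K` successes in a universe of `N`.
#'
#' @param k,K,n_draw,N Table counts.
#' @return List with `p_upper`, `p_lower`.
#' @export
hyper_tails <- function(k, K, n_draw, N) {
  list(p_upper = stats::phyper(k - 1, K, N - K, n_draw, lower.tail = FALSE),
       p_lower = stats::phyper(k, K, N - K, n_draw, lower.tail = TRUE))
}

#' Per-disease enrichment of strong GWAS variants near a region set
#'
#' For every disease, builds the 2x2 table of {strongly associated vs not} x
#' {nearby the target vs not} over the tested variant universe, takes the
#' exact hypergeometric tail (upper for enrichment, lower for depletion),
#' BH-adjusts the smaller tail across diseases, and reports the signed
#' `-log10` adjusted p (positive = enrichment, negative = depletion).
#'
#' @param panel Named list of per-disease data frames with columns `variant`
#'   and `p` (or a p-value matrix, variants x diseases).
#' @param variants Data frame of the variant universe: `variant`, `chrom`,
#'   `pos` (0-based).
#' @param target `GRanges` region set.
#' @param p_strong Threshold defining a strong association (default 1e-5).
#' @param window Proximity window in bp (default 10000).
#' @return Data frame, one row per disease: `disease`, `k`, `K`, `n_near`,
#'   `N`, `p`, `fdr`, `direction`, `signed_log10_fdr`, `degenerate`.
#' @export
per_disease_enrichment <- function(panel, variants, target, p_strong = 1e-5,
                                   window = 10000) {
  if (!length(target)) stop("empty target region set")
  if (is.matrix(panel) || is.data.frame(panel)) {
    pm <- as.matrix(panel)
    panel <- lapply(stats::setNames(seq_len(ncol(pm)), colnames(pm)),
                    function(j) data.frame(variant = rownames(pm),
                                           p = pm[, j]))
  }
  near <- near_region_flags(variants$chrom, variants$pos, target,
                            window = window)
  names(near) <- variants$variant
  rows <- lapply(names(panel), function(ds) {
    d <- panel[[ds]]
    d <- d[d$variant %in% variants$variant & !is.na(d$p), , drop = FALSE]
    nr <- near[d$variant]
    N <- nrow(d)
    n_near <- sum(nr)
    strong <- d$p <= p_strong
    K <- sum(strong)
    k <- sum(strong & nr)
    degen <- n_near == 0 || n_near == N || K == 0 || K == N
    tl <- hyper_tails(k, K, n_near, N)
    data.frame(disease = ds, k = k, K = K, n_near = n_near, N = N,
               p = min(tl$p_upper, tl$p_lower),
               direction = if (tl$p_upper <= tl$p_lower) 1 else -1,
               degenerate = degen, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out$signed_log10_fdr <- out$direction * -log10(out$fdr)
  out
}

#' Contrast cross-set scores between variant groups
#'
#' Summarizes `z_cross` per nearest-set group and runs all pairwise
#' two-sided Mann-Whitney tests with BH adjustment. When both the unaltered
#' open-chromatin group and the non-accessible group are present, reports the
#' control ordering check (accessible-but-unaltered vs non-accessible).
#'
#' @param scores Data frame from [cross_set_metric()].
#' @param groups Character vector of group labels aligned with `scores` rows
#'   (e.g. from [nearest_set_label()]).
#' @param control_pair Length-2 labels for the control ordering check
#'   (default `c("unaltered", "none")`).
#' @return List with `summary` (per-group n/mean/median), `tests` (pairwise
#'   data frame), and `control_check` (one-sided test that the first control
#'   label exceeds the second, or `NULL`).
#' @export
group_contrast <- function(scores, groups,
                           control_pair = c("unaltered", "none")) {
  stopifnot(length(groups) == nrow(scores))
  z <- scores$z_cross
  ok <- !is.na(z)
  z <- z[ok]; groups <- groups[ok]
  labs <- sort(unique(groups))
  summ <- data.frame(group = labs,
                     n = as.integer(table(groups)[labs]),
                     mean = as.numeric(tapply(z, groups, mean)[labs]),
                     median = as.numeric(tapply(z, groups, median)[labs]),
                     stringsAsFactors = FALSE)
  tests <- list()
  for (i in seq_along(labs)) for (j in seq_along(labs)) {
    if (i >= j) next
    xa <- z[groups == labs[i]]; xb <- z[groups == labs[j]]
    if (length(xa) < 2 || length(xb) < 2) next
    ct <- compare_sets(xa, xb)
    tests[[length(tests) + 1]] <- data.frame(
      group_a = labs[i], group_b = labs[j], U = ct$U, effect = ct$effect,
      p = ct$p, stringsAsFactors = FALSE)
  }
  tests <- if (length(tests)) do.call(rbind, tests) else NULL
  if (!is.null(tests)) tests$fdr <- stats::p.adjust(tests$p, method = "BH")
  control <- NULL
  if (all(control_pair %in% labs)) {
    xa <- z[groups == control_pair[1]]
    xb <- z[groups == control_pair[2]]
    if (length(xa) >= 2 && length(xb) >= 2) {
      wt <- stats::wilcox.test(xa, xb, alternative = "greater",
                               exact = FALSE, correct = FALSE)
      control <- list(greater = control_pair[1], lesser = control_pair[2],
                      p = wt$p.value,
                      effect = unname(wt$statistic) /
                        (length(xa) * length(xb)))
    }
  }
  list(summary = summ, tests = tests, control_check = control)
}
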