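## ---------------------------------------------------------------------------
## Evolutionary characterization of region sets: per-region conservation,
## per-bp permutation enrichment against randomized backgrounds, common-variant
## density, per-variant profile contrasts, and the CDF shift test.
## ---------------------------------------------------------------------------

#' Per-region mean conservation score
#'
#' Averages a per-base score track over each region. Bases without track
#' coverage are skipped (not zero-filled) and the covered fraction is
#' reported; regions with no covered base get `NA`.
#'
#' @param regions `GRanges`.
#' @param track Data frame in bedGraph layout: `chrom`, `start`, `end`
#'   (0-based half-open), `score`, or a `GRanges` with a `score` column.
#' @return Data frame with `region` (index), `mean_score`,
#'   `covered_fraction`, `n_covered_bp`.
#' @export
region_conservation <- function(regions, track) {
  if (is.data.frame(track)) {
    tg <- GenomicRanges::GRanges(track$chrom,
                                 IRanges::IRanges(track$start + 1L, track$end))
    S4Vectors::mcols(tg)$score <- track$score
  } else {
    tg <- track
  }
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(regions, tg, ignore.strand = TRUE))
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ovw <- GenomicRanges::width(IRanges::pintersect(
    GenomicRanges::ranges(regions)[qi], GenomicRanges::ranges(tg)[si]))
  sc <- S4Vectors::mcols(tg)$score[si]
  wsum <- tapply(ovw * sc, qi, sum)
  bsum <- tapply(ovw, qi, sum)
  n <- length(regions)
  mean_score <- rep(NA_real_, n)
  covered <- rep(0, n)
  idx <- as.integer(names(wsum))
  mean_score[idx] <- as.numeric(wsum) / as.numeric(bsum)
  covered[idx] <- as.numeric(bsum)
  data.frame(region = seq_len(n),
             mean_score = mean_score,
             covered_fraction = covered / GenomicRanges::width(regions),
             n_covered_bp = covered)
}

#' Rank-based comparison of a per-region metric between two sets
#'
#' Two-sided Mann-Whitney U with the common-language effect size
#' (probability that a value from `a` exceeds one from `b`, ties counted
#' half).
#'
#' @param a,b Numeric vectors (at least 2 values each; `NA` dropped).
#' @return List with `U`, `p`, `effect` (common-language effect size),
#'   `n_a`, `n_b`.
#' @export
compare_sets <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) stop("need >= 2 values per set")
  wt <- stats::wilcox.test(a, b, exact = FALSE, correct = FALSE)
  U <- unname(wt$statistic)
  list(U = U, p = wt$p.value, effect = U / (length(a) * length(b)),
       n_a = length(a), n_b = length(b))
}

#' Per-bp feature enrichment against randomized backgrounds
#'
#' The observed statistic is the per-bp overlap of the target with the
#' feature, `overlap_bp(target, feature) / total_bp(target)`; the null is the
#' same statistic over length- and chromosome-preserving randomizations of
#' the target ([shuffle_regions()]). `empirical_p` is the smaller one-tail
#' probability `(1 + #{null at least as extreme}) / (n_perm + 1)` (so its
#' floor is `1/(n_perm+1)`); `p_two_sided` doubles it, capped at 1.
#'
#' @param target,feature `GRanges` region sets.
#' @param chrom_sizes Named chromosome lengths.
#' @param n_perm Number of randomizations (>= 1).
#' @param seed Optional seed.
#' @param exclude Optional exclusion mask for placements.
#' @return Data frame row: `target_label`, `feature_label`,
#'   `observed_per_bp`, `null_mean_per_bp`, `fold`, `direction`,
#'   `empirical_p`, `p_two_sided`, `n_perm`.
#' @export
feature_enrichment <- function(target, feature, chrom_sizes, n_perm = 100,
                               seed = NULL, exclude = NULL) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  tbp <- total_bp(target)
  if (tbp == 0) stop("empty target")
  obs <- overlap_bp(target, feature) / tbp
  shuf <- shuffle_regions(target, chrom_sizes, n_perm, exclude = exclude,
                          seed = seed)
  # each draw is normalized by its own union size, so the whole-genome
  # feature gives fold = 1 identically
  null <- vapply(shuf, function(g) overlap_bp(g, feature) / total_bp(g),
                 numeric(1))
  p_up <- (1 + sum(null >= obs)) / (n_perm + 1)
  p_dn <- (1 + sum(null <= obs)) / (n_perm + 1)
  nm <- mean(null)
  data.frame(target_label = set_label(target),
             feature_label = set_label(feature),
             observed_per_bp = obs,
             null_mean_per_bp = nm,
             fold = if (nm > 0) obs / nm else NA_real_,
             direction = if (p_up <= p_dn) 1 else -1,
             empirical_p = min(p_up, p_dn),
             p_two_sided = min(1, 2 * min(p_up, p_dn)),
             n_perm = n_perm,
             stringsAsFactors = FALSE)
}

#' Common-variant density within a region set
#'
#' Counts variants passing the minor-allele-frequency threshold that fall
#' inside the target, per bp of target sequence, and compares it to shuffled
#' backgrounds and (optionally) to named feature sets.
#'
#' @param target `GRanges`.
#' @param variants Data frame with `chrom`, `pos` (0-based), `maf`.
#' @param chrom_sizes Named chromosome lengths.
#' @param maf_cut Inclusive MAF threshold for "common" (default 0.05).
#' @param n_perm Shuffled backgrounds for the null (default 100; 0 skips).
#' @param features Optional named list of `GRanges` reference feature sets
#'   (introns, promoter-TSS, repeats, ...) whose densities are reported
#'   alongside.
#' @param seed Optional seed.
#' @return List with `density` (per-bp), `n_variants`, `null`
#'   (data frame from the permutation comparison or `NULL`), and
#'   `feature_density` (named vector or `NULL`).
#' @export
variant_density <- function(target, variants, chrom_sizes, maf_cut = 0.05,
                            n_perm = 100, features = NULL, seed = NULL) {
  pass <- variants[variants$maf >= maf_cut, , drop = FALSE]
  dens_in <- function(gr) {
    if (!nrow(pass)) return(0)
    sum(near_region_flags(pass$chrom, pass$pos, gr, window = 0)) /
      total_bp(gr)
  }
  obs <- dens_in(target)
  nulldf <- NULL
  if (n_perm > 0) {
    shuf <- shuffle_regions(target, chrom_sizes, n_perm, seed = seed)
    null <- vapply(shuf, dens_in, numeric(1))
    p_up <- (1 + sum(null >= obs)) / (n_perm + 1)
    p_dn <- (1 + sum(null <= obs)) / (n_perm + 1)
    nulldf <- data.frame(null_mean = mean(null), null_sd = stats::sd(null),
                         fold = if (mean(null) > 0) obs / mean(null) else NA,
                         empirical_p = min(p_up, p_dn),
                         p_two_sided = min(1, 2 * min(p_up, p_dn)),
                         direction = if (p_up <= p_dn) 1 else -1)
  }
  fd <- NULL
  if (!is.null(features))
    fd <- vapply(features, dens_in, numeric(1))
  list(density = obs,
       n_variants = if (nrow(pass)) sum(near_region_flags(
         pass$chrom, pass$pos, target, window = 0)) else 0L,
       null = nulldf, feature_density = fd)
}

#' Annotate variants with an evolutionary profile
#'
#' Flags conserved-element membership, carries allele age and per-bp
#' functional score, and assigns the nearest region-set label under the
#' shared proximity rule.
#'
#' @param variants Data frame with `variant`, `chrom`, `pos` (0-based), and
#'   optional `allele_age`, `functional_score` columns.
#' @param conserved `GRanges` of conserved elements.
#' @param region_sets Named list of `GRanges` for nearest-set assignment.
#' @param window Proximity window in bp (default 10000).
#' @return The input data frame plus `in_conserved_element` and
#'   `nearest_set`.
#' @export
variant_profiles <- function(variants, conserved, region_sets,
                             window = 10000) {
  variants$in_conserved_element <-
    near_region_flags(variants$chrom, variants$pos, conserved, window = 0)
  variants$nearest_set <- nearest_set_label(variants$chrom, variants$pos,
                                            region_sets, window = window)
  variants
}

#' Group contrasts of per-variant evolutionary metrics
#'
#' For each metric, reports per-group means and all pairwise two-sided
#' Mann-Whitney tests between nearest-set labels, BH-adjusted within metric,
#' plus conserved-element membership rates per group.
#'
#' @param profiles Data frame from [variant_profiles()] (needs
#'   `nearest_set`; metrics taken from `metrics`).
#' @param metrics Character vector of numeric columns to contrast.
#' @return List with `group_means` (group x metric), `membership_rate`
#'   (per group), and `tests` (long data frame of pairwise results).
#' @export
variant_profile_contrast <- function(profiles,
                                     metrics = c("allele_age",
                                                 "functional_score",
                                                 "z_cross")) {
  metrics <- intersect(metrics, names(profiles))
  grp <- profiles$nearest_set
  labs <- sort(unique(grp))
  small <- names(which(table(grp) < 2))
  if (length(small))
    warning("groups with < 2 members skipped in tests: ",
            paste(small, collapse = ", "))
  gm <- sapply(metrics, function(m) tapply(profiles[[m]], grp, mean,
                                           na.rm = TRUE))
  mr <- tapply(profiles$in_conserved_element, grp, mean)
  tests <- list()
  for (m in metrics) {
    for (i in seq_along(labs)) for (j in seq_along(labs)) {
      if (i >= j) next
      xa <- profiles[[m]][grp == labs[i]]
      xb <- profiles[[m]][grp == labs[j]]
      if (sum(!is.na(xa)) < 2 || sum(!is.na(xb)) < 2) next
      ct <- compare_sets(xa, xb)
      tests[[length(tests) + 1]] <- data.frame(
        metric = m, group_a = labs[i], group_b = labs[j],
        U = ct$U, effect = ct$effect, p = ct$p, stringsAsFactors = FALSE)
    }
  }
  tests <- if (length(tests)) do.call(rbind, tests) else NULL
  if (!is.null(tests)) {
    tests$fdr <- NA_real_
    for (m in unique(tests$metric)) {
      k <- tests$metric == m
      tests$fdr[k] <- stats::p.adjust(tests$p[k], method = "BH")
    }
  }
  list(group_means = gm, membership_rate = mr, tests = tests)
}

#' CDF shift test of a target score vector against a baseline population
#'
#' Fits a normal distribution (mean, sd) to the baseline scores and tests the
#' target scores against that reference CDF with a one-sample
#' Kolmogorov-Smirnov test. Reports the fold-change of `-log10(p)` relative
#' to the same test run on the full baseline (the "all variants" test), so
#' the all-variants test against itself has fold-change 1.
#'
#' @param target Numeric scores for the focal variant set.
#' @param baseline Numeric scores for the reference population.
#' @param min_n Below this many target scores the result is flagged
#'   low-power (default 5).
#' @return List with `p`, `p_baseline`, `log10_fold_change`, `statistic`,
#'   `n`, `low_power`.
#' @export
cdf_shift_test <- function(target, baseline, min_n = 5) {
  target <- target[!is.na(target)]
  baseline <- baseline[!is.na(baseline)]
  mu <- mean(baseline)
  sdev <- stats::sd(baseline)
  kt <- suppressWarnings(stats::ks.test(target, "pnorm", mu, sdev))
  kb <- suppressWarnings(stats::ks.test(baseline, "pnorm", mu, sdev))
  list(p = kt$p.value,
       p_baseline = kb$p.value,
       log10_fold_change = (-log10(kt$p.value)) / (-log10(kb$p.value)),
       statistic = unname(kt$statistic),
       n = length(target),
       low_power = length(target) < min_n)
}
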