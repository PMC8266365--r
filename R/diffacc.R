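## ---------------------------------------------------------------------------
## Differential accessibility: peak consolidation, log-CPM normalization,
## empirical-Bayes moderated linear fits, stage/age set calling, the
## directionality-sharing test, and promoter-level accessibility.
## ---------------------------------------------------------------------------

#' Consolidate per-replicate peak calls into reproducible regions
#'
#' Within each tissue/stage group, a base is retained when covered by peaks in
#' at least `min_support` replicates; the retained regions are then unioned
#' across groups and merged. This is the reproducibility filter applied before
#' any differential testing.
#'
#' @param peaks Named list of `GRanges`, one per replicate peak call.
#' @param meta Data frame with one row per element of `peaks` and columns
#'   `sample_id` (matching `names(peaks)`), `tissue`, `stage`.
#' @param min_support Minimum number of replicates supporting a base within a
#'   tissue/stage group (default 2). Groups with fewer replicates than
#'   `min_support` use all their replicates (i.e. the support threshold is
#'   capped at the group size).
#' @return Merged `GRanges` of reproducible regions.
#' @export
consolidate_peaks <- function(peaks, meta, min_support = 2L) {
  if (!length(peaks)) stop("empty peak list")
  stopifnot(all(meta$sample_id %in% names(peaks)))
  grp <- interaction(meta$tissue, meta$stage, drop = TRUE)
  kept <- list()
  for (g in levels(grp)) {
    ids <- meta$sample_id[grp == g]
    sup <- min(min_support, length(ids))
    # count each replicate once per base
    reps <- lapply(peaks[ids], GenomicRanges::reduce)
    cov <- GenomicRanges::coverage(suppressWarnings(do.call(c, unname(reps))))
    sl <- IRanges::slice(cov, lower = sup, rangesOnly = TRUE)
    kept[[g]] <- GenomicRanges::GRanges(sl)
  }
  merge_regions(suppressWarnings(do.call(c, unname(kept))))
}

#' Log2-CPM normalization with optional precision weights
#'
#' Scales each sample by library size and returns
#' `log2((count + pseudocount) / (libsize + 2 * pseudocount) * 1e6)`.
#' When `weights = TRUE`, per-observation precision weights are computed from
#' a lowess trend of sqrt residual standard deviation against average
#' log-count, in the style of variance-modelling count pipelines: the trend is
#' evaluated at each fitted log-count and the weight is its inverse fourth
#' power.
#'
#' @param counts Integer matrix, regions x samples.
#' @param design Model matrix used to compute residual standard deviations for
#'   the weight trend (required when `weights = TRUE`).
#' @param pseudocount Added to counts before the log (default 0.5).
#' @param weights Compute precision weights (default `FALSE`).
#' @return List with `logcpm` (matrix), `lib_size` (vector), and `weights`
#'   (matrix or `NULL`), plus `trend` (the lowess fit) when weights are on.
#' @export
normalize_counts <- function(counts, design = NULL, pseudocount = 0.5,
                             weights = FALSE) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative counts")
  lib <- colSums(counts)
  if (any(lib == 0)) stop("zero library size")
  logcpm <- t(log2(t(counts + pseudocount) / (lib + 2 * pseudocount) * 1e6))
  out <- list(logcpm = logcpm, lib_size = lib, weights = NULL)
  if (weights) {
    if (is.null(design)) stop("design required for precision weights")
    fit <- stats::lm.fit(design, t(logcpm))
    res <- t(fit$residuals)
    dfr <- nrow(design) - fit$rank
    sqrtsd <- sqrt(sqrt(rowSums(res^2) / dfr))
    # mean-variance trend on the average log count scale
    avelog <- rowMeans(logcpm) + mean(log2(lib + 1)) - log2(1e6)
    lo <- stats::lowess(avelog, sqrtsd, f = 0.5)
    fitted_cpm <- t(design %*% fit$coefficients)  # regions x samples
    fitted_log <- sweep(fitted_cpm, 2, log2(lib + 1), "+") - log2(1e6)
    ap <- stats::approx(lo$x, lo$y, xout = as.vector(fitted_log), rule = 2)
    w <- matrix(ap$y, nrow(logcpm), ncol(logcpm))
    out$weights <- 1 / w^4
    out$trend <- lo
  }
  out
}

## -- empirical-Bayes machinery ----------------------------------------------

#' Invert the trigamma function
#'
#' Newton iteration solving `trigamma(y) = x` for `y > 0`, used when
#' moment-matching the variance prior.
#'
#' @param x Positive numeric vector.
#' @return `y` with `trigamma(y) = x`.
#' @export
trigamma_inverse <- function(x) {
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (max(abs(dif / y)) < 1e-10) break
  }
  y
}

#' Moment-match a scaled-F prior to observed sample variances
#'
#' Estimates the prior degrees of freedom `d0` and prior variance `s02` of the
#' hierarchical model `s2 ~ s02 * F(df, d0)` from the moments of
#' `log(s2)`. Returns `d0 = Inf` when the observed log-variances are no more
#' dispersed than sampling noise alone.
#'
#' @param s2 Vector of residual sample variances.
#' @param df Residual degrees of freedom (scalar or vector).
#' @return List with `d0` and `s02`.
#' @export
fit_variance_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2) stop("need at least two positive variances")
  s2 <- s2[ok]
  df <- rep_len(df, length(ok))[ok]
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  ebar <- mean(e)
  evar <- sum((e - ebar)^2) / (length(e) - 1)
  resid_var <- evar - mean(trigamma(df / 2))
  if (resid_var > 0) {
    d0 <- 2 * trigamma_inverse(resid_var)
    s02 <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s02 <- exp(ebar)
  }
  list(d0 = d0, s02 = s02)
}

#' Empirical-Bayes moderated linear fit
#'
#' Per-region least squares on a shared design, followed by shrinkage of
#' residual variances toward a common prior:
#' `s2_post = (d0 * s02 + df * s2) / (d0 + df)`, with the moderated t on
#' `d0 + df` degrees of freedom. The prior `(d0, s02)` is estimated by
#' moment-matching the scaled-F distribution of the sample variances
#' ([fit_variance_prior()]) unless supplied.
#'
#' @param logmat Numeric matrix, regions x samples (e.g. log2-CPM).
#' @param design Model matrix (samples x coefficients), full rank.
#' @param coef Column of `design` to test (default 2).
#' @param weights Optional precision-weight matrix matching `logmat`.
#' @param d0,s02 Optional prior overrides. `d0 = 0` gives the ordinary
#'   per-region t; `d0 = Inf` with fixed `s02` gives the pooled prior-variance
#'   t (normal reference).
#' @return Data frame with one row per region: `region`, `log2fc`,
#'   `moderated_t`, `p`, `fdr`, `direction`, plus `s2`, `df_total` and the
#'   prior in attributes.
#' @export
moderated_fit <- function(logmat, design, coef = 2, weights = NULL,
                          d0 = NULL, s02 = NULL) {
  logmat <- as.matrix(logmat)
  design <- as.matrix(design)
  n <- ncol(logmat)
  stopifnot(nrow(design) == n)
  p <- qr(design)$rank
  if (p < ncol(design)) stop("rank-deficient design")
  dfr <- n - p
  if (dfr < 1) stop("no residual degrees of freedom")

  if (is.null(weights)) {
    fit <- stats::lm.fit(design, t(logmat))
    beta <- t(fit$coefficients)[, coef]
    res <- t(fit$residuals)
    s2 <- rowSums(res^2) / dfr
    xtxi <- chol2inv(chol(crossprod(design)))
    su <- sqrt(xtxi[coef, coef])
    su <- rep(su, nrow(logmat))
  } else {
    weights <- as.matrix(weights)
    stopifnot(dim(weights) == dim(logmat))
    beta <- numeric(nrow(logmat))
    s2 <- numeric(nrow(logmat))
    su <- numeric(nrow(logmat))
    for (i in seq_len(nrow(logmat))) {
      w <- weights[i, ]
      f <- stats::lm.wfit(design, logmat[i, ], w)
      beta[i] <- f$coefficients[coef]
      s2[i] <- sum(w * f$residuals^2) / dfr
      xtxi <- chol2inv(chol(crossprod(design * sqrt(w))))
      su[i] <- sqrt(xtxi[coef, coef])
    }
  }

  if (any(!is.finite(s2))) stop("non-finite residual variance")
  if (all(s2 == 0)) stop("all regions constant")

  if (is.null(d0) || is.null(s02)) {
    prior <- fit_variance_prior(s2[s2 > 0], dfr)
    if (is.null(d0)) d0 <- prior$d0
    if (is.null(s02)) s02 <- prior$s02
  }

  if (is.infinite(d0)) {
    s2post <- rep(s02, length(s2))
    df_total <- Inf
  } else if (d0 == 0) {
    s2post <- s2
    df_total <- dfr
  } else {
    s2post <- (d0 * s02 + dfr * s2) / (d0 + dfr)
    df_total <- d0 + dfr
  }

  tstat <- beta / (su * sqrt(s2post))
  pval <- 2 * stats::pt(-abs(tstat), df = df_total)
  out <- data.frame(
    region = if (!is.null(rownames(logmat))) rownames(logmat)
             else paste0("r", seq_len(nrow(logmat))),
    log2fc = beta,
    moderated_t = tstat,
    p = pval,
    fdr = stats::p.adjust(pval, method = "BH"),
    direction = sign(beta),
    s2 = s2,
    stringsAsFactors = FALSE
  )
  attr(out, "prior") <- list(d0 = d0, s02 = s02, df_residual = dfr,
                             df_total = df_total)
  out
}

#' Build the stage design matrix
#'
#' Intercept + adult-stage indicator, with tissue as additive covariates so
#' that the stage contrast is pan-tissue.
#'
#' @param meta Sample sheet with `stage` (`"fetal"`/`"adult"`) and `tissue`.
#' @return Model matrix; the tested coefficient is column 2 (`stageadult`).
#' @export
stage_design <- function(meta) {
  meta$stage <- factor(meta$stage, levels = c("fetal", "adult"))
  if (length(unique(meta$tissue)) > 1) {
    stats::model.matrix(~ stage + factor(tissue), data = meta)
  } else {
    stats::model.matrix(~ stage, data = meta)
  }
}

#' Call stage-biased region sets from a moderated fit
#'
#' Significant regions (BH FDR below `fdr_cut`) are partitioned by direction:
#' positive adult-vs-fetal log2 fold-change gives the adult-biased set,
#' negative the fetal-biased set.
#'
#' @param results Data frame from [moderated_fit()].
#' @param regions `GRanges` aligned with `results` rows (optional; when
#'   missing, index vectors are returned instead of `GRanges`).
#' @param fdr_cut FDR threshold (default 0.05).
#' @param labels Length-2 labels for the (positive, negative) sets.
#' @return List with elements named by `labels` (region sets or index
#'   vectors) and the logical significance mask `sig`.
#' @export
call_stage_sets <- function(results, regions = NULL, fdr_cut = 0.05,
                            labels = c("adult_biased", "fetal_biased")) {
  sig <- !is.na(results$fdr) & results$fdr < fdr_cut
  up <- sig & results$log2fc > 0
  dn <- sig & results$log2fc < 0
  if (is.null(regions)) {
    out <- list(which(up), which(dn))
  } else {
    stopifnot(length(regions) == nrow(results))
    out <- list(region_set(GenomicRanges::sort(regions[up]), labels[1]),
                region_set(GenomicRanges::sort(regions[dn]), labels[2]))
  }
  names(out) <- labels
  out$sig <- sig
  out
}

#' Nested young/old contrast within developmentally-altered regions
#'
#' Restricts to adult samples, splits them at `age_split` years (younger than
#' the split is "young", older is "old"), and reruns the moderated engine on
#' the developmentally-altered regions only, with BH correction within that
#' restricted family.
#'
#' @param logmat Log-scale matrix, regions x samples (all samples).
#' @param meta Sample sheet with `stage`, `tissue` and `age` (years, adults).
#' @param dev_idx Indices (or logical mask) of developmentally-altered
#'   regions.
#' @param age_split Age split in years (default 50; ages strictly below are
#'   young, ages above are old; exact ties go to old).
#' @param weights Optional precision weights (full matrix; subset internally).
#' @return List with `results` (data frame over `dev_idx` rows, columns as in
#'   [moderated_fit()]) and `meta_adult` (the adult sample sheet with the
#'   derived `age_group`).
#' @export
nested_age_contrast <- function(logmat, meta, dev_idx, age_split = 50,
                                weights = NULL) {
  adult <- meta$stage == "adult"
  if (!any(adult)) stop("no adult samples")
  ma <- meta[adult, , drop = FALSE]
  if (any(is.na(ma$age))) stop("adult samples missing ages")
  ma$age_group <- factor(ifelse(ma$age < age_split, "young", "old"),
                         levels = c("young", "old"))
  if (length(unique(ma$age_group)) < 2) stop("one age group empty")
  if (is.logical(dev_idx)) dev_idx <- which(dev_idx)
  if (!length(dev_idx)) stop("no developmentally-altered regions supplied")
  sub <- logmat[dev_idx, adult, drop = FALSE]
  des <- if (length(unique(ma$tissue)) > 1) {
    stats::model.matrix(~ age_group + factor(tissue), data = ma)
  } else {
    stats::model.matrix(~ age_group, data = ma)
  }
  w <- if (is.null(weights)) NULL else weights[dev_idx, adult, drop = FALSE]
  res <- moderated_fit(sub, des, coef = 2, weights = w)
  res$region_index <- dev_idx
  list(results = res, meta_adult = ma)
}

#' Directionality-sharing test between two contrasts
#'
#' For regions significant in both the developmental and the age contrast,
#' cross-tabulates the two direction labels and tests association with a
#' Pearson chi-square on 1 df (Yates continuity correction off by default).
#'
#' @param dev_direction,age_direction Sign vectors (+1/-1) over the same
#'   regions, typically already restricted to doubly-significant regions.
#' @param correct Apply the Yates continuity correction (default `FALSE`).
#' @return List with `table` (2x2), `statistic`, `p`, and `undefined`
#'   (`TRUE` with a `reason` when a margin is zero).
#' @export
directionality_test <- function(dev_direction, age_direction,
                                correct = FALSE) {
  stopifnot(length(dev_direction) == length(age_direction))
  tb <- table(factor(sign(dev_direction), levels = c(-1, 1)),
              factor(sign(age_direction), levels = c(-1, 1)))
  if (any(rowSums(tb) == 0) || any(colSums(tb) == 0)) {
    return(list(table = tb, statistic = NA_real_, p = NA_real_,
                undefined = TRUE, reason = "zero margin in 2x2 table"))
  }
  ct <- suppressWarnings(stats::chisq.test(tb, correct = correct))
  list(table = tb, statistic = unname(ct$statistic), p = unname(ct$p.value),
       undefined = FALSE)
}

#' Promoter windows from TSS annotations
#'
#' Pads each transcription start site 1 kb up- and downstream (half-open
#' window `(tss - pad, tss + pad]` in 0-based coordinates).
#'
#' @param genes Data frame with `gene`, `chrom`, `tss` (0-based position),
#'   optional `strand`.
#' @param pad Flank in bp (default 1000).
#' @return `GRanges` with a `gene` metadata column.
#' @export
promoter_windows <- function(genes, pad = 1000) {
  if (any(is.na(genes$tss))) stop("missing TSS")
  gr <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(pmax(1, genes$tss - pad + 1), genes$tss + pad))
  S4Vectors::mcols(gr)$gene <- genes$gene
  gr
}

#' Promoter-level differential accessibility
#'
#' Runs the moderated engine on a promoter-window count matrix (one row per
#' promoter, built upstream by counting reads in [promoter_windows()]).
#'
#' @param promoter_counts Counts matrix, promoters x samples.
#' @param meta Sample sheet (see [stage_design()]).
#' @param fdr_cut Significance threshold (default 0.05).
#' @return Data frame from [moderated_fit()] with a `significant` column.
#' @export
promoter_accessibility <- function(promoter_counts, meta, fdr_cut = 0.05) {
  nc <- normalize_counts(promoter_counts)
  res <- moderated_fit(nc$logcpm, stage_design(meta), coef = 2)
  res$significant <- !is.na(res$fdr) & res$fdr < fdr_cut
  res
}
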