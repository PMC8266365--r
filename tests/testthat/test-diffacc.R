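make_meta <- function(n_tissues = 2, reps = 3) {
  meta <- expand.grid(replicate = seq_len(reps),
                      stage = c("fetal", "adult"),
                      tissue = paste0("t", seq_len(n_tissues)),
                      stringsAsFactors = FALSE)
  meta$sample_id <- paste(meta$tissue, meta$stage, meta$replicate, sep = "_")
  meta$age <- ifelse(meta$stage == "adult",
                     ifelse(meta$replicate %% 2 == 1, 30, 65), NA)
  meta
}

test_that("peak consolidation matches brute-force per-bp support counting", {
  set.seed(21)
  meta <- make_meta(n_tissues = 2, reps = 3)
  peaks <- lapply(seq_len(nrow(meta)), function(i)
    make_gr(random_intervals(30, tiny_genome, max_w = 80)))
  names(peaks) <- meta$sample_id
  for (ms in c(1L, 2L)) {
    got <- consolidate_peaks(peaks, meta, min_support = ms)
    # oracle: per-bp replicate support within each tissue/stage group
    grp <- split(meta$sample_id, paste(meta$tissue, meta$stage))
    keep <- lapply(tiny_genome, function(L) logical(L))
    for (ids in grp) {
      support <- lapply(tiny_genome, function(L) integer(L))
      for (id in ids) {
        bm <- bitmap_of(gr_df(peaks[[id]]), tiny_genome)
        for (ch in names(support))
          support[[ch]] <- support[[ch]] + bm[[ch]]
      }
      for (ch in names(keep))
        keep[[ch]] <- keep[[ch]] | (support[[ch]] >= ms)
    }
    got_bm <- bitmap_of(gr_df(got), tiny_genome)
    for (ch in names(keep)) expect_equal(got_bm[[ch]], keep[[ch]])
  }
  # min_support = 1 is the merged union of everything
  u <- consolidate_peaks(peaks, meta, min_support = 1L)
  all_df <- do.call(rbind, lapply(peaks, gr_df))
  expect_equal(total_bp(u), bitmap_union_bp(all_df, tiny_genome))
  # a peak in 1 of 3 replicates is dropped at min_support = 2
  one_rep <- c(list(GenomicRanges::GRanges("chrA", IRanges::IRanges(1, 50))),
               rep(list(GenomicRanges::GRanges("chrB",
                                              IRanges::IRanges(1, 50))), 5))
  names(one_rep) <- meta$sample_id[1:6]
  got <- consolidate_peaks(one_rep, meta[1:6, ], min_support = 2L)
  expect_false(any(as.character(GenomicRanges::seqnames(got)) == "chrA"))
  expect_error(consolidate_peaks(list(), meta), "empty")
})

test_that("log2-CPM normalization follows the library-size scaling law", {
  cm <- matrix(100L, 10, 4, dimnames = list(paste0("r", 1:10),
                                            paste0("s", 1:4)))
  nc <- normalize_counts(cm)
  # equal counts and equal libraries: constant matrix
  expect_equal(max(nc$logcpm) - min(nc$logcpm), 0)
  # doubling one sample's library shifts its column down by one log2 unit
  cm2 <- cm
  cm2[, 2] <- 200L
  nc2 <- normalize_counts(cm2)
  expect_equal(nc2$logcpm[, 1] - nc$logcpm[, 1], rep(0, 10),
               ignore_attr = TRUE)
  expect_error(normalize_counts(matrix(0L, 3, 2)), "zero library")
  # agrees with the established count pipeline's log-CPM up to the
  # pseudocount convention on a random matrix
  skip_if_not_installed("edgeR")
  set.seed(5)
  cm3 <- matrix(rnbinom(200, mu = 100, size = 10), 50, 4)
  ours <- normalize_counts(cm3)$logcpm
  ref <- edgeR::cpm(cm3, log = TRUE, prior.count = 0.5)
  expect_equal(unname(ours), unname(ref), tolerance = 0.02)
})

test_that("precision weights reproduce the fitted mean-variance trend", {
  set.seed(31)
  meta <- make_meta()
  des <- stage_design(meta)
  cm <- matrix(rnbinom(300 * nrow(meta), mu = 150, size = 5), 300,
               nrow(meta), dimnames = list(NULL, meta$sample_id))
  nc <- normalize_counts(cm, design = des, weights = TRUE)
  expect_equal(dim(nc$weights), dim(cm))
  expect_true(all(nc$weights > 0))
  # refit oracle: recompute the trend independently and evaluate it
  fit <- lm.fit(des, t(nc$logcpm))
  sqrtsd <- sqrt(sqrt(colSums(fit$residuals^2) / (nrow(des) - fit$rank)))
  avelog <- rowMeans(nc$logcpm) + mean(log2(colSums(cm) + 1)) - log2(1e6)
  lo <- lowess(avelog, sqrtsd, f = 0.5)
  expect_equal(nc$trend$y, lo$y)
})

test_that("moderated t collapses to ordinary t at d0 = 0", {
  set.seed(41)
  meta <- make_meta(n_tissues = 1, reps = 4)
  des <- stage_design(meta)
  y <- matrix(rnorm(50 * nrow(meta)), 50, nrow(meta))
  res <- moderated_fit(y, des, d0 = 0, s02 = 1)
  adult <- meta$stage == "adult"
  for (i in c(1, 17, 50)) {
    tt <- t.test(y[i, adult], y[i, !adult], var.equal = TRUE)
    expect_equal(res$moderated_t[i], unname(tt$statistic),
                 tolerance = 1e-10)
    expect_equal(res$p[i], tt$p.value, tolerance = 1e-10)
  }
})

test_that("moderated t collapses to the pooled-variance z at d0 = Inf", {
  set.seed(43)
  meta <- make_meta(n_tissues = 1, reps = 4)
  des <- stage_design(meta)
  y <- matrix(rnorm(50 * nrow(meta)), 50, nrow(meta))
  s02 <- 0.9
  res <- moderated_fit(y, des, d0 = Inf, s02 = s02)
  fit <- lm.fit(des, t(y))
  beta <- t(fit$coefficients)[, 2]
  su <- sqrt(chol2inv(chol(crossprod(des)))[2, 2])
  expect_equal(res$moderated_t, beta / (su * sqrt(s02)), tolerance = 1e-12)
  expect_equal(res$p, 2 * pnorm(-abs(res$moderated_t)), tolerance = 1e-12)
})

test_that("moderated fit agrees with the reference empirical-Bayes engine", {
  skip_if_not_installed("limma")
  set.seed(47)
  meta <- make_meta(n_tissues = 2, reps = 3)
  des <- stage_design(meta)
  y <- matrix(rnorm(400 * nrow(meta), sd = rep(exp(rnorm(400, 0, 0.4)),
                                               nrow(meta))),
              400, nrow(meta))
  ours <- moderated_fit(y, des)
  lf <- limma::eBayes(limma::lmFit(y, des))
  expect_equal(attr(ours, "prior")$d0, lf$df.prior, tolerance = 1e-6)
  expect_equal(attr(ours, "prior")$s02, lf$s2.prior, tolerance = 1e-6)
  expect_equal(ours$moderated_t, lf$t[, 2], ignore_attr = TRUE,
               tolerance = 1e-8)
  expect_equal(ours$p, lf$p.value[, 2], ignore_attr = TRUE,
               tolerance = 1e-8)
})

test_that("moderated fit rejects degenerate designs", {
  meta <- make_meta(n_tissues = 1, reps = 2)
  des <- cbind(stage_design(meta), dup = stage_design(meta)[, 2])
  y <- matrix(rnorm(10 * nrow(meta)), 10, nrow(meta))
  expect_error(moderated_fit(y, des), "rank-deficient")
  expect_error(moderated_fit(matrix(1, 5, 4),
                             stage_design(make_meta(1, 2))),
               "constant")
})

test_that("null simulation gives uniform p and unbiased log2fc", {
  set.seed(53)
  meta <- make_meta(n_tissues = 2, reps = 3)
  cm <- matrix(rnbinom(500 * nrow(meta), mu = 200, size = 10), 500,
               nrow(meta), dimnames = list(NULL, meta$sample_id))
  nc <- normalize_counts(cm)
  res <- moderated_fit(nc$logcpm, stage_design(meta))
  expect_gt(ks.test(res$p, "punif")$p.value, 1e-3)
  expect_lt(abs(mean(res$log2fc)), 3 * sd(res$log2fc) / sqrt(500))
})

test_that("results are invariant to sample and region order", {
  set.seed(59)
  meta <- make_meta()
  cm <- matrix(rnbinom(100 * nrow(meta), mu = 100, size = 5), 100,
               nrow(meta), dimnames = list(paste0("r", 1:100),
                                           meta$sample_id))
  nc <- normalize_counts(cm)
  res1 <- moderated_fit(nc$logcpm, stage_design(meta))
  perm <- sample(nrow(meta))
  res2 <- moderated_fit(nc$logcpm[, perm], stage_design(meta[perm, ]))
  expect_equal(res1$moderated_t, res2$moderated_t, tolerance = 1e-12)
  rperm <- sample(100)
  res3 <- moderated_fit(nc$logcpm[rperm, ], stage_design(meta))
  expect_equal(res3$p[order(rperm)], res1$p, tolerance = 1e-12)
})

test_that("stage sets partition significant regions by direction", {
  res <- data.frame(region = paste0("r", 1:4),
                    log2fc = c(2, -1, 3, 0.5),
                    fdr = c(0.04, 0.01, 0.2, 0.049))
  sets <- call_stage_sets(res, fdr_cut = 0.05)
  expect_equal(sets$adult_biased, c(1, 4))
  expect_equal(sets$fetal_biased, 2)
  none <- call_stage_sets(res, fdr_cut = 0)
  expect_length(none$adult_biased, 0)
  expect_length(none$fetal_biased, 0)
})

test_that("age split at 50 sends 49 to young and 51 to old", {
  set.seed(61)
  meta <- make_meta(n_tissues = 1, reps = 4)
  meta$age[meta$stage == "adult"] <- c(49, 51, 30, 70)
  y <- matrix(rnorm(20 * nrow(meta)), 20, nrow(meta),
              dimnames = list(NULL, meta$sample_id))
  nag <- nested_age_contrast(y, meta, dev_idx = 1:10)
  expect_equal(as.character(nag$meta_adult$age_group),
               c("young", "old", "young", "old"))
  meta$age[meta$stage == "adult"] <- c(20, 25, 30, 35)
  expect_error(nested_age_contrast(y, meta, 1:10), "age group empty")
})

test_that("nested null contrast is calibrated at ~5% false positives", {
  set.seed(67)
  fp <- replicate(10, {
    meta <- make_meta(n_tissues = 2, reps = 4)
    y <- matrix(rnorm(300 * nrow(meta)), 300, nrow(meta),
                dimnames = list(NULL, meta$sample_id))
    nag <- nested_age_contrast(y, meta, dev_idx = 1:300)
    mean(nag$results$p < 0.05)
  })
  expect_lt(mean(fp), 0.075)
  expect_gt(mean(fp), 0.025)
})

test_that("directionality chi-square matches hand computation", {
  # perfectly shared directions, 50/50 table
  d <- rep(c(-1, 1), each = 50)
  r1 <- directionality_test(d, d, correct = FALSE)
  expect_equal(unname(r1$statistic), 100)
  r2 <- directionality_test(d, d, correct = TRUE)
  expect_equal(unname(r2$statistic), 96.04)
  # independent balanced table has statistic 0
  a <- rep(c(-1, 1), 50)
  b <- rep(c(-1, -1, 1, 1), 25)
  expect_lt(directionality_test(a, b)$statistic, 1e-10)
  # zero margin is reported undefined, not an error
  r3 <- directionality_test(rep(1, 10), rep(c(-1, 1), 5))
  expect_true(r3$undefined)
})

test_that("promoter windows pad the TSS 1 kb each side", {
  g <- data.frame(gene = "g1", chrom = "chr1", tss = 5000)
  w <- promoter_windows(g, pad = 1000)
  expect_equal(gr_df(w), data.frame(chrom = "chr1", start = 4000,
                                    end = 6000))
  expect_error(promoter_windows(data.frame(gene = "g", chrom = "c",
                                           tss = NA)), "missing TSS")
})
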