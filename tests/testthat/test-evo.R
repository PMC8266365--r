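test_that("per-region conservation means match the per-bp loop oracle", {
  # constant track: every region averages to the constant
  reg <- make_gr(data.frame(chrom = "chrA", start = c(0, 100),
                            end = c(50, 160)))
  tr <- data.frame(chrom = "chrA", start = 0, end = 1000, score = 2.5)
  rc <- region_conservation(reg, tr)
  expect_equal(rc$mean_score, c(2.5, 2.5))
  expect_equal(rc$covered_fraction, c(1, 1))
  # half 0 / half 1
  tr2 <- data.frame(chrom = "chrA", start = c(0, 25), end = c(25, 50),
                    score = c(0, 1))
  expect_equal(region_conservation(reg[1], tr2)$mean_score, 0.5)
  # random track vs per-bp loop
  set.seed(127)
  bins <- data.frame(chrom = "chrA", start = seq(0, 990, 10),
                     end = seq(10, 1000, 10), score = rnorm(100))
  regions <- make_gr(data.frame(chrom = "chrA", start = c(5, 200, 995),
                                end = c(95, 310, 1000)))
  rc2 <- region_conservation(regions, bins)
  perbp <- numeric(1000)
  for (i in seq_len(nrow(bins)))
    perbp[(bins$start[i] + 1):bins$end[i]] <- bins$score[i]
  rdf <- gr_df(regions)
  for (i in 1:3)
    expect_equal(rc2$mean_score[i],
                 mean(perbp[(rdf$start[i] + 1):rdf$end[i]]))
  # a region with no covered base is missing, and counted as such
  gap <- make_gr(data.frame(chrom = "chrB", start = 0, end = 10))
  rc3 <- region_conservation(gap, bins)
  expect_true(is.na(rc3$mean_score))
  expect_equal(rc3$covered_fraction, 0)
})

test_that("rank comparison equals brute-force pair counting and detects
           shifts", {
  set.seed(131)
  for (i in 1:5) {
    a <- rnorm(sample(5:50, 1))
    b <- rnorm(sample(5:50, 1))
    cs <- compare_sets(a, b)
    expect_equal(cs$U, u_oracle(a, b))
    expect_equal(cs$effect, u_oracle(a, b) / (length(a) * length(b)))
  }
  a <- rnorm(200)
  expect_lt(compare_sets(a + 1, a)$p, 1e-6)
  expect_error(compare_sets(1, rnorm(5)), ">= 2 values")
})

test_that("feature enrichment has exact identities at the extremes", {
  genome <- c(chrA = 10000)
  target <- region_set(data.frame(chrom = "chrA",
                                  start = seq(0, 900, 100) * 10,
                                  end = seq(0, 900, 100) * 10 + 50))
  whole <- genome_regions(genome)
  r <- feature_enrichment(target, whole, genome, n_perm = 20, seed = 1)
  expect_equal(r$fold, 1)        # feature = genome: fold exactly 1
  expect_equal(r$observed_per_bp, 1)
  # empirical p floor is 1/(n_perm+1)
  r99 <- feature_enrichment(target, target, genome, n_perm = 99, seed = 2)
  expect_gte(r99$empirical_p, 1 / 100)
  expect_error(feature_enrichment(target, whole, genome, n_perm = 0),
               "n_perm")
})

test_that("enrichment fold approaches the analytic expectation when the
           target sits inside a feature covering 10% of the genome", {
  genome <- c(chrA = 1e5)
  feature <- region_set(data.frame(chrom = "chrA", start = 0, end = 1e4))
  target <- region_set(data.frame(chrom = "chrA",
                                  start = seq(100, 9000, 500),
                                  end = seq(100, 9000, 500) + 60))
  r <- feature_enrichment(target, feature, genome, n_perm = 400, seed = 3)
  expect_equal(r$observed_per_bp, 1)
  expect_equal(r$fold, 10, tolerance = 0.25)
  expect_lte(r$empirical_p, 0.01)
  expect_equal(r$direction, 1)
})

test_that("common-variant density honors the MAF threshold and matches a
           uniform-rate expectation", {
  genome <- c(chrA = 10000)
  target <- region_set(data.frame(chrom = "chrA", start = 1000, end = 3000))
  v <- data.frame(chrom = "chrA", pos = c(1500, 2000, 2500),
                  maf = c(0.049, 0.05, 0.2))
  vd <- variant_density(target, v, genome, maf_cut = 0.05, n_perm = 0)
  expect_equal(vd$n_variants, 2L)    # MAF 0.049 excluded at >= 0.05
  expect_equal(vd$density, 2 / 2000)
  empty <- variant_density(target, v[0, ], genome, n_perm = 0)
  expect_equal(empty$density, 0)
  # uniform variants at rate lambda: density ~ lambda and the null CI
  # covers it
  set.seed(137)
  vu <- data.frame(chrom = "chrA", pos = floor(runif(500) * 10000),
                   maf = 0.3)
  vdu <- variant_density(target, vu, genome, n_perm = 200, seed = 7)
  expect_equal(vdu$density, 0.05, tolerance = 0.25)
  expect_gt(vdu$null$p_two_sided, 0.05)
})

test_that("variant profiles recover planted conservation/age structure with
           correct signs", {
  # strong planted contrast so the signs are unambiguous at desk scale
  cfg <- sim_config(n_regions = 400, n_variants = 30000, n_diseases = 6,
                    chrom_len = 2e5, conservation_shift = 1.5,
                    age_mixing = 1, seed = 19)
  acc <- simulate_accessibility(cfg)
  gw <- simulate_gwas_panel(cfg, acc)
  tk <- simulate_tracks(cfg, acc, gw$variants)
  lab <- acc$truth$region_labels
  sets <- list(
    adult_biased = region_set(acc$regions[lab == "adult"], "adult_biased"),
    fetal_biased = region_set(acc$regions[lab == "fetal"], "fetal_biased"))
  # window 0: profile variants falling inside the region sets themselves
  pr <- variant_profiles(tk$variants, tk$conserved, sets, window = 0)
  ctr <- variant_profile_contrast(pr, metrics = c("allele_age",
                                                  "functional_score"))
  gm <- ctr$group_means
  # fetal-biased neighborhoods: more conserved-element membership, younger
  # alleles, higher functional scores
  expect_gt(ctr$membership_rate["fetal_biased"],
            ctr$membership_rate["adult_biased"])
  expect_lt(gm["fetal_biased", "allele_age"], gm["adult_biased", "allele_age"])
  expect_gt(gm["fetal_biased", "functional_score"],
            gm["adult_biased", "functional_score"])
  # membership flags equal a brute-force interval lookup
  cdf <- gr_df(tk$conserved)
  idx <- sample(nrow(pr), 200)
  want <- vapply(idx, function(i) {
    any(cdf$chrom == pr$chrom[i] & pr$pos[i] >= cdf$start &
          pr$pos[i] < cdf$end)
  }, logical(1))
  expect_equal(pr$in_conserved_element[idx], want)
})

test_that("identical groups show no profile contrast beyond the nominal
           rate", {
  set.seed(139)
  pr <- data.frame(chrom = "chrA", pos = 1:600,
                   nearest_set = sample(c("a", "b", "c"), 600, TRUE),
                   in_conserved_element = sample(c(TRUE, FALSE), 600, TRUE),
                   allele_age = rexp(600), functional_score = runif(600))
  ctr <- variant_profile_contrast(pr, metrics = c("allele_age",
                                                  "functional_score"))
  expect_lt(mean(ctr$tests$p < 0.05), 0.25)
})

test_that("CDF shift test is calibrated, powered, and self-normalizing", {
  set.seed(149)
  baseline <- rnorm(5000)
  # target drawn from the baseline distribution: p roughly uniform
  ps <- replicate(50, cdf_shift_test(rnorm(80), baseline)$p)
  expect_gt(mean(ps > 0.05), 0.8)
  # +1 sd shift at n = 100 is decisively rejected
  sh <- cdf_shift_test(rnorm(100, 1), baseline)
  expect_lt(sh$p, 1e-3)
  # the all-variants test against itself has fold-change exactly 1
  self <- cdf_shift_test(baseline, baseline)
  expect_equal(self$log10_fold_change, 1)
  expect_true(cdf_shift_test(rnorm(3), baseline)$low_power)
})
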