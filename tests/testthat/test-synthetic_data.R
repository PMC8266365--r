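test_that("config validation enforces the stated invariants", {
  expect_error(sim_config(dispersion = 0), "dispersion")
  expect_error(sim_config(frac_adult_biased = 0.7, frac_fetal_biased = 0.5),
               "<= 1")
  expect_error(sim_config(n_regions = 0), "counts")
  expect_error(sim_config(chrom_len = 100, region_width = 300), "exceed")
  expect_error(sim_config(frac_pleiotropic = 1.2), "frac_pleiotropic")
})

test_that("the generator is deterministic under a fixed seed", {
  cfg <- sim_config(n_regions = 100, n_variants = 500, n_diseases = 4,
                    chrom_len = 1e5, n_genes = 40, seed = 23)
  s1 <- simulate_all(cfg)
  s2 <- simulate_all(cfg)
  expect_identical(s1$acc$counts, s2$acc$counts)
  expect_identical(s1$gwas$pmat, s2$gwas$pmat)
  expect_identical(s1$tracks$track, s2$tracks$track)
  expect_identical(s1$truth, s2$truth)
  cfg2 <- sim_config(n_regions = 100, n_variants = 500, n_diseases = 4,
                     chrom_len = 1e5, n_genes = 40, seed = 24)
  s3 <- simulate_all(cfg2)
  expect_false(identical(s1$acc$counts, s3$acc$counts))
  expect_false(identical(s1$tracks$track$score, s3$tracks$track$score))
})

test_that("planted labels cover every region and every planted variant sits
           near its assigned class", {
  cfg <- sim_config(n_regions = 300, n_variants = 2000, chrom_len = 2e5,
                    seed = 29)
  acc <- simulate_accessibility(cfg)
  expect_length(acc$truth$region_labels, cfg$n_regions)
  expect_true(all(acc$truth$region_labels %in% c("adult", "fetal", "null")))
  # nested age labels only on developmentally-altered regions
  nested <- acc$truth$nested_age_labels
  expect_true(all(names(which(nested != "null")) %in%
                    names(which(acc$truth$region_labels != "null"))))
  gw <- simulate_gwas_panel(cfg, acc)
  target <- acc$regions[acc$truth$region_labels == "adult"]
  pv <- gw$variants[gw$variants$variant %in% gw$truth$pleiotropic_variants, ]
  near <- near_region_flags(pv$chrom, pv$pos, target,
                            window = cfg$proximity_window)
  expect_true(all(near))
  # regions never overlap each other
  expect_equal(total_bp(acc$regions),
               sum(GenomicRanges::width(acc$regions)))
})

test_that("a global-null configuration yields calibrated downstream calls", {
  cfg <- sim_config(n_regions = 600, frac_adult_biased = 0,
                    frac_fetal_biased = 0, effect_logfc = 0, seed = 31)
  acc <- simulate_accessibility(cfg)
  nc <- normalize_counts(acc$counts)
  res <- moderated_fit(nc$logcpm, stage_design(acc$meta))
  expect_gt(ks.test(res$p, "punif")$p.value, 1e-4)
  expect_lt(mean(res$fdr < 0.05), 0.02)  # BH under the global null
})

test_that("null GWAS panels give uniform p-values and a null cross-set
           metric", {
  cfg <- sim_config(n_variants = 5000, n_diseases = 10, frac_pleiotropic = 0,
                    seed = 37)
  acc <- simulate_accessibility(cfg)
  gw <- simulate_gwas_panel(cfg, acc)
  expect_gt(ks.test(gw$pmat[, 1], "punif")$p.value, 1e-4)
  z <- cross_set_metric(gw$pmat)$z_cross
  expect_lt(abs(mean(z)), 0.05)
  # zero pleiotropy strength: the "pleiotropic" subset is indistinguishable
  cfg0 <- sim_config(n_variants = 5000, n_diseases = 10,
                     pleiotropy_strength = 0, frac_pleiotropic = 0.05,
                     seed = 41)
  gw0 <- simulate_gwas_panel(cfg0, simulate_accessibility(cfg0))
  z0 <- cross_set_metric(gw0$pmat)$z_cross
  pl <- gw0$variants$variant %in% gw0$truth$pleiotropic_variants
  expect_gt(wilcox.test(z0[pl], z0[!pl])$p.value, 0.01)
})

test_that("MAF spectrum puts mass on both sides of the common threshold", {
  cfg <- sim_config(n_variants = 5000, seed = 43)
  gw <- simulate_gwas_panel(cfg, simulate_accessibility(cfg))
  expect_gt(mean(gw$variants$maf >= 0.05), 0.2)
  expect_gt(mean(gw$variants$maf < 0.05), 0.2)
  expect_true(all(gw$variants$maf > 0 & gw$variants$maf <= 0.5))
})

test_that("the conservation shift is recovered within the closed-form CI", {
  cfg <- sim_config(n_regions = 500, n_variants = 1000, chrom_len = 2e5,
                    conservation_shift = 0.5, seed = 47)
  acc <- simulate_accessibility(cfg)
  gw <- simulate_gwas_panel(cfg, acc)
  tk <- simulate_tracks(cfg, acc, gw$variants)
  rc <- region_conservation(acc$regions, tk$track)
  lab <- acc$truth$region_labels
  mf <- mean(rc$mean_score[lab == "fetal"])
  ma <- mean(rc$mean_score[lab == "adult"])
  # per-region means average ~300 iid N(mu, 1) bases; the difference of
  # class means is 0.5 with standard error sqrt(2/(n_regions*width))-ish
  n_per <- sum(lab == "fetal")
  se <- sqrt(2 / (n_per * cfg$region_width / cfg$track_bin))
  expect_lt(abs((mf - ma) - cfg$conservation_shift), 4 * se + 0.02)
  # zero mixing weight leaves allele age independent of membership
  cfg0 <- sim_config(n_variants = 4000, age_mixing = 0, seed = 53)
  acc0 <- simulate_accessibility(cfg0)
  gw0 <- simulate_gwas_panel(cfg0, acc0)
  tk0 <- simulate_tracks(cfg0, acc0, gw0$variants)
  wt <- wilcox.test(tk0$variants$allele_age[tk0$variants$in_conserved_element],
                    tk0$variants$allele_age[!tk0$variants$in_conserved_element])
  expect_gt(wt$p.value, 0.001)
})

test_that("planted stage-biased regions are recovered at high sensitivity", {
  cfg <- sim_config(seed = 59)  # default study conditions
  acc <- simulate_accessibility(cfg)
  nc <- normalize_counts(acc$counts)
  res <- moderated_fit(nc$logcpm, stage_design(acc$meta))
  sets <- call_stage_sets(res, fdr_cut = 0.05)
  lab <- acc$truth$region_labels
  tp <- (lab == "adult" & seq_along(lab) %in% sets$adult_biased) |
    (lab == "fetal" & seq_along(lab) %in% sets$fetal_biased)
  expect_gt(sum(tp) / sum(lab != "null"), 0.8)
  called <- sets$sig
  expect_lt(sum(called & lab == "null") / max(1, sum(called)), 0.15)
})

test_that("simulation round-trips through the on-disk dialects", {
  cfg <- sim_config(n_regions = 60, n_variants = 300, n_diseases = 3,
                    chrom_len = 5e4, n_genes = 25, n_core_genes = 5,
                    seed = 61)
  sim <- simulate_all(cfg)
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  back <- read_simulation(dir)
  expect_equal(unname(back$acc$counts), unname(sim$acc$counts))
  expect_equal(gr_df(back$acc$regions), gr_df(sim$acc$regions))
  expect_equal(back$gwas$panel$disease1$p, sim$gwas$panel$disease1$p,
               tolerance = 1e-6)
  expect_equal(unlist(back$truth$region_labels),
               sim$truth$region_labels)
  expect_length(back$peaks, nrow(sim$acc$meta))
})
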