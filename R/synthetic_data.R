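## ---------------------------------------------------------------------------
## Synthetic-data generator. Produces every input the pipeline consumes, with
## planted structure (stage-biased regions, nested age shifts, pleiotropic
## GWAS variants, conservation shifts, core genes) so each downstream stage
## has recoverable ground truth.
## ---------------------------------------------------------------------------

#' Simulation configuration
#'
#' Bundles every generator parameter with validated defaults. The defaults
#' describe the study conditions the package's planted-recovery checks run
#' under: 3 tissues x 2 stages x 4 replicates, 10% adult-biased and 10%
#' fetal-biased regions at log2 fold-change 2 on negative-binomial counts
#' (dispersion 0.1), half the developmentally-altered regions carrying a
#' nested young/old shift that shares the developmental direction 80% of the
#' time, 20 diseases with 2% pleiotropic variants at expected |Z| = 3, and a
#' +0.5 conservation shift in fetal-biased regions.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_len Chromosome length in bp.
#' @param n_regions Number of accessible regions.
#' @param region_width Region width in bp.
#' @param n_tissues Number of tissues (each with fetal and adult samples).
#' @param replicates_per_group Replicates per tissue/stage group.
#' @param frac_adult_biased,frac_fetal_biased Proportions of planted
#'   stage-biased regions (sum must be <= 1).
#' @param effect_logfc Planted adult-vs-fetal log2 fold-change magnitude.
#' @param dispersion Negative-binomial dispersion (> 0).
#' @param baseline_log2_mean,baseline_log2_sd Log-normal baseline
#'   accessibility (log2 scale).
#' @param frac_age_shifted Fraction of developmentally-altered regions that
#'   also carry a young/old shift.
#' @param frac_share_direction Probability the nested age shift shares the
#'   developmental direction (adult-biased -> old-biased).
#' @param age_effect_logfc Magnitude of the nested young/old shift.
#' @param n_variants Number of variants.
#' @param n_diseases Number of disease GWAS panels.
#' @param frac_pleiotropic Fraction of variants planted as pleiotropic.
#' @param pleiotropy_strength Expected |Z| of pleiotropic variants in
#'   affected diseases.
#' @param frac_disease_affected Fraction of diseases in which a pleiotropic
#'   variant carries signal (majority by default).
#' @param pleiotropy_target Region class pleiotropic variants are placed
#'   near (`"adult_biased"` by default).
#' @param proximity_window Shared "nearby" window in bp.
#' @param conservation_shift Mean per-bp conservation added inside
#'   fetal-biased regions.
#' @param conserved_quantile Track quantile above which conserved elements
#'   are emitted.
#' @param age_mixing Mixing weight anti-correlating allele age with
#'   conserved-element membership (0 = none).
#' @param track_bin Conservation-track bin width in bp.
#' @param n_genes Number of genes.
#' @param n_core_genes Number of planted core genes (loci seeded with
#'   pleiotropic variants).
#' @param locus_window Gene locus half-width in bp.
#' @param seed Integer seed; each generator stage derives its stream from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_chrom = 4L, chrom_len = 5e5, n_regions = 2000L,
                       region_width = 300L, n_tissues = 3L,
                       replicates_per_group = 4L,
                       frac_adult_biased = 0.1, frac_fetal_biased = 0.1,
                       effect_logfc = 2, dispersion = 0.1,
                       baseline_log2_mean = 6, baseline_log2_sd = 1,
                       frac_age_shifted = 0.5, frac_share_direction = 0.8,
                       age_effect_logfc = 2,
                       n_variants = 20000L, n_diseases = 20L,
                       frac_pleiotropic = 0.02, pleiotropy_strength = 3,
                       frac_disease_affected = 0.7,
                       pleiotropy_target = "adult_biased",
                       proximity_window = 10000,
                       conservation_shift = 0.5, conserved_quantile = 0.9,
                       age_mixing = 0.5, track_bin = 10L,
                       n_genes = 300L, n_core_genes = 20L,
                       locus_window = 1e5, seed = 1L) {
  cfg <- as.list(environment())
  counts <- c("n_chrom", "n_regions", "n_tissues", "replicates_per_group",
              "n_variants", "n_diseases", "n_genes")
  if (any(unlist(cfg[counts]) < 1)) stop("all counts must be >= 1")
  if (cfg$dispersion <= 0) stop("dispersion must be positive")
  if (cfg$frac_adult_biased + cfg$frac_fetal_biased > 1)
    stop("frac_adult_biased + frac_fetal_biased must be <= 1")
  if (cfg$chrom_len <= cfg$region_width)
    stop("chrom_len must exceed region width")
  for (f in c("frac_adult_biased", "frac_fetal_biased", "frac_age_shifted",
              "frac_share_direction", "frac_pleiotropic",
              "frac_disease_affected"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must be in [0, 1]")
  structure(cfg, class = "sim_config")
}

#' Chromosome sizes of a simulated genome
#' @param cfg `sim_config`.
#' @return Named numeric vector.
#' @export
sim_chrom_sizes <- function(cfg) {
  stats::setNames(rep(cfg$chrom_len, cfg$n_chrom),
                  paste0("chr", seq_len(cfg$n_chrom)))
}

# Non-overlapping region placement: even grid with uniform jitter inside
# each slot, so regions never collide and placement is near-uniform.
place_regions <- function(cfg) {
  per_chrom <- ceiling(cfg$n_regions / cfg$n_chrom)
  slot <- floor(cfg$chrom_len / per_chrom)
  if (slot <= cfg$region_width)
    stop("chrom_len too small for n_regions regions of this width")
  chrom <- rep(paste0("chr", seq_len(cfg$n_chrom)), each = per_chrom)
  slot_start <- rep((seq_len(per_chrom) - 1) * slot, cfg$n_chrom)
  keep <- seq_len(cfg$n_regions)
  chrom <- chrom[keep]; slot_start <- slot_start[keep]
  jit <- floor(runif(cfg$n_regions) * (slot - cfg$region_width))
  st <- slot_start + jit  # 0-based
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(st + 1, st + cfg$region_width))
  S4Vectors::mcols(gr)$name <- paste0("r", seq_len(cfg$n_regions))
  GenomicRanges::sort(gr)
}

#' Simulate accessibility counts with planted stage-biased regions
#'
#' Places non-overlapping regions, assigns planted labels (adult-biased,
#' fetal-biased, null) and nested age labels, and draws negative-binomial
#' counts whose log2 mean carries `+effect_logfc` in adult samples for
#' adult-biased regions, `-effect_logfc` for fetal-biased, 0 for null
#' regions; nested age shifts act on adult samples split young/old.
#'
#' @param cfg `sim_config`.
#' @return List with `counts` (regions x samples), `meta` (sample sheet with
#'   `sample_id`, `tissue`, `stage`, `age`, `replicate`), `regions`
#'   (`GRanges`), `chrom_sizes`, `truth` (list: `region_labels`,
#'   `nested_age_labels`, `dev_direction`, `age_direction`), and `cfg`.
#' @export
simulate_accessibility <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  regions <- place_regions(cfg)
  n <- cfg$n_regions

  n_ad <- round(n * cfg$frac_adult_biased)
  n_fe <- round(n * cfg$frac_fetal_biased)
  lab <- rep("null", n)
  planted <- sample.int(n, n_ad + n_fe)
  lab[planted[seq_len(n_ad)]] <- "adult"
  if (n_fe > 0) lab[planted[n_ad + seq_len(n_fe)]] <- "fetal"
  beta <- ifelse(lab == "adult", cfg$effect_logfc,
                 ifelse(lab == "fetal", -cfg$effect_logfc, 0))

  # nested young/old shifts within the developmentally-altered regions
  age_lab <- rep("null", n)
  gamma <- rep(0, n)
  dev <- which(lab != "null")
  if (length(dev)) {
    shifted <- dev[runif(length(dev)) < cfg$frac_age_shifted]
    share <- runif(length(shifted)) < cfg$frac_share_direction
    # sharing direction: adult-biased -> old-biased, fetal-biased -> young
    dir_dev <- beta[shifted] > 0
    old_up <- ifelse(share, dir_dev, !dir_dev)
    age_lab[shifted] <- ifelse(old_up, "old", "young")
    gamma[shifted] <- ifelse(old_up, cfg$age_effect_logfc,
                             -cfg$age_effect_logfc)
  }

  # sample sheet: tissues x stages x replicates; adult ages alternate
  # young/old so both age groups are present in every tissue
  meta <- expand.grid(replicate = seq_len(cfg$replicates_per_group),
                      stage = c("fetal", "adult"),
                      tissue = paste0("tissue", seq_len(cfg$n_tissues)),
                      stringsAsFactors = FALSE)
  meta$sample_id <- paste(meta$tissue, meta$stage, meta$replicate, sep = "_")
  meta$age <- NA_real_
  ad <- meta$stage == "adult"
  young <- ad & (meta$replicate %% 2 == 1)
  old <- ad & (meta$replicate %% 2 == 0)
  meta$age[young] <- round(runif(sum(young), 25, 45), 1)
  meta$age[old] <- round(runif(sum(old), 55, 75), 1)
  meta <- meta[, c("sample_id", "tissue", "stage", "age", "replicate")]

  baseline <- rnorm(n, cfg$baseline_log2_mean, cfg$baseline_log2_sd)
  libf <- runif(nrow(meta), 0.7, 1.3)
  is_adult <- as.numeric(meta$stage == "adult")
  is_old <- as.numeric(!is.na(meta$age) & meta$age >= 50)
  # centered indicators keep the baseline the grand mean
  log2mu <- outer(baseline, rep(1, nrow(meta))) +
    outer(beta, is_adult - 0.5) +
    outer(gamma, ifelse(is_adult == 1, is_old - 0.5, 0))
  mu <- t(t(2^log2mu) * libf)
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / cfg$dispersion),
                   nrow = n,
                   dimnames = list(S4Vectors::mcols(regions)$name,
                                   meta$sample_id))
  list(counts = counts, meta = meta, regions = regions,
       chrom_sizes = sim_chrom_sizes(cfg),
       truth = list(region_labels = stats::setNames(
                      lab, S4Vectors::mcols(regions)$name),
                    nested_age_labels = stats::setNames(
                      age_lab, S4Vectors::mcols(regions)$name),
                    dev_direction = beta, age_direction = gamma),
       cfg = cfg)
}

#' Simulate per-replicate peak calls around the true regions
#'
#' Each replicate observes each true region with probability `p_detect`
#' (boundaries jittered) and adds replicate-private noise peaks, so the
#' consolidation step has real work to do.
#'
#' @param cfg `sim_config`.
#' @param regions `GRanges` of true regions.
#' @param meta Sample sheet from [simulate_accessibility()].
#' @param p_detect Per-replicate detection probability (default 0.9).
#' @param n_noise Noise peaks per replicate (default 20).
#' @param jitter Max boundary jitter in bp (default 20).
#' @return Named list of `GRanges`, one per sample in `meta`.
#' @export
simulate_peak_calls <- function(cfg, regions, meta, p_detect = 0.9,
                                n_noise = 20L, jitter = 20L) {
  set.seed(cfg$seed + 7L)
  sizes <- sim_chrom_sizes(cfg)
  out <- lapply(meta$sample_id, function(id) {
    det <- runif(length(regions)) < p_detect
    gr <- regions[det]
    j1 <- sample(-jitter:jitter, length(gr), replace = TRUE)
    j2 <- sample(-jitter:jitter, length(gr), replace = TRUE)
    st <- pmax(1, GenomicRanges::start(gr) + j1)
    en <- pmax(st + 1, GenomicRanges::end(gr) + j2)
    noise_chr <- sample(names(sizes), n_noise, replace = TRUE)
    noise_st <- floor(runif(n_noise) * (sizes[noise_chr] - 200)) + 1
    g <- suppressWarnings(c(
      GenomicRanges::GRanges(as.character(GenomicRanges::seqnames(gr)),
                             IRanges::IRanges(st, en)),
      GenomicRanges::GRanges(noise_chr,
                             IRanges::IRanges(noise_st, noise_st + 199))))
    GenomicRanges::sort(g)
  })
  stats::setNames(out, meta$sample_id)
}

#' Simulate a variant table and per-disease GWAS panels
#'
#' Variants are placed uniformly; a planted pleiotropic subset is relocated
#' near regions of the target class and receives Z-scores with expected
#' magnitude `pleiotropy_strength` (random sign per disease) in a majority of
#' diseases; everything else is standard normal. Minor allele frequencies are
#' drawn log-uniform on [0.005, 0.5], putting mass on both sides of the 0.05
#' common-variant threshold.
#'
#' @param cfg `sim_config`.
#' @param sim Result of [simulate_accessibility()] (for regions and truth).
#' @return List with `variants` (data frame: `variant`, `chrom`, `pos`,
#'   `maf`), `panel` (named list of per-disease data frames: `variant`,
#'   `chrom`, `pos`, `beta`, `p`), `pmat` (variants x diseases p matrix),
#'   and `truth$pleiotropic_variants`.
#' @export
simulate_gwas_panel <- function(cfg, sim) {
  if (!length(sim$regions)) stop("regions are empty")
  set.seed(cfg$seed + 13L)
  sizes <- sim$chrom_sizes
  nv <- cfg$n_variants
  chrom <- sample(names(sizes), nv, replace = TRUE)
  pos <- floor(runif(nv) * sizes[chrom])  # 0-based
  ids <- paste0("v", seq_len(nv))

  n_pleio <- round(nv * cfg$frac_pleiotropic)
  pleio <- sample.int(nv, n_pleio)
  target <- sim$regions[sim$truth$region_labels ==
                          sub("_biased$", "", cfg$pleiotropy_target)]
  if (length(target) && n_pleio) {
    anchor <- sample(seq_along(target), n_pleio, replace = TRUE)
    off <- floor(runif(n_pleio, -cfg$proximity_window / 2,
                       cfg$proximity_window / 2))
    chrom[pleio] <- as.character(GenomicRanges::seqnames(target))[anchor]
    pos[pleio] <- pmax(0, pmin(sizes[chrom[pleio]] - 1,
                               GenomicRanges::start(target)[anchor] - 1 + off))
  }
  maf <- exp(runif(nv, log(0.005), log(0.5)))

  Z <- matrix(rnorm(nv * cfg$n_diseases), nv, cfg$n_diseases)
  if (n_pleio && cfg$pleiotropy_strength > 0) {
    for (i in pleio) {
      hit <- runif(cfg$n_diseases) < cfg$frac_disease_affected
      sgn <- sample(c(-1, 1), cfg$n_diseases, replace = TRUE)
      Z[i, hit] <- Z[i, hit] + sgn[hit] * cfg$pleiotropy_strength
    }
  }
  pmat <- 2 * pnorm(-abs(Z))
  dimnames(pmat) <- list(ids, paste0("disease", seq_len(cfg$n_diseases)))
  panel <- lapply(stats::setNames(seq_len(cfg$n_diseases), colnames(pmat)),
                  function(j) data.frame(variant = ids, chrom = chrom,
                                         pos = pos, beta = Z[, j] * 0.01,
                                         p = pmat[, j],
                                         stringsAsFactors = FALSE))
  list(variants = data.frame(variant = ids, chrom = chrom, pos = pos,
                             maf = maf, stringsAsFactors = FALSE),
       panel = panel, pmat = pmat,
       truth = list(pleiotropic_variants = ids[pleio]))
}

#' Simulate conservation, allele-age and functional-score annotations
#'
#' The per-bp conservation track (emitted in `track_bin` bins) is standard
#' normal plus `conservation_shift` inside fetal-biased regions; conserved
#' elements are the merged bins exceeding the `conserved_quantile` track
#' quantile; allele age is exponential with mean lowered inside conserved
#' elements by the mixing weight; the per-variant functional score follows
#' local conservation plus noise.
#'
#' @param cfg `sim_config`.
#' @param sim Result of [simulate_accessibility()].
#' @param variants Variant table from [simulate_gwas_panel()].
#' @return List with `track` (data frame `chrom`, `start`, `end`, `score`),
#'   `conserved` (`GRanges`), and `variants` (input plus `allele_age`,
#'   `functional_score`, `in_conserved_element`).
#' @export
simulate_tracks <- function(cfg, sim, variants) {
  set.seed(cfg$seed + 29L)
  bin <- cfg$track_bin
  reg <- sim$regions
  lab <- sim$truth$region_labels
  # binned track covering the region footprint
  nb <- ceiling(GenomicRanges::width(reg) / bin)
  chrom <- rep(as.character(GenomicRanges::seqnames(reg)), nb)
  reg_id <- rep(seq_along(reg), nb)
  off <- unlist(lapply(nb, function(k) seq_len(k) - 1)) * bin
  st <- GenomicRanges::start(reg)[reg_id] - 1 + off
  en <- pmin(st + bin, GenomicRanges::end(reg)[reg_id])
  mu <- ifelse(lab[reg_id] == "fetal", cfg$conservation_shift, 0)
  score <- rnorm(length(st), mu, 1)
  track <- data.frame(chrom = chrom, start = st, end = en, score = score,
                      stringsAsFactors = FALSE)
  thr <- stats::quantile(score, cfg$conserved_quantile)
  cons <- merge_regions(GenomicRanges::GRanges(
    chrom[score > thr], IRanges::IRanges(st[score > thr] + 1,
                                         en[score > thr])))
  attr(cons, "label") <- "conserved_element"

  v <- variants
  inel <- near_region_flags(v$chrom, v$pos, cons, window = 0)
  base_age <- 1000
  mean_age <- base_age * ifelse(inel, 1 - cfg$age_mixing / 2,
                                1 + cfg$age_mixing / 2)
  v$allele_age <- rexp(nrow(v), rate = 1 / mean_age)
  # functional score tracks local conservation
  tg <- GenomicRanges::GRanges(track$chrom,
                               IRanges::IRanges(track$start + 1L, track$end))
  S4Vectors::mcols(tg)$score <- track$score
  pts <- GenomicRanges::GRanges(v$chrom, IRanges::IRanges(v$pos + 1, v$pos + 1))
  hit <- suppressWarnings(
    GenomicRanges::findOverlaps(pts, tg, ignore.strand = TRUE,
                                select = "first"))
  local_cons <- ifelse(is.na(hit), 0, S4Vectors::mcols(tg)$score[hit])
  v$functional_score <- stats::plogis(local_cons + rnorm(nrow(v), 0, 0.5))
  v$in_conserved_element <- inel
  list(track = track, conserved = cons, variants = v)
}

#' Simulate gene annotations, capture pairs, and planted core genes
#'
#' Genes get uniform TSS positions; planted core genes have their TSS placed
#' next to pleiotropic variants so their loci harbor strong cross-disease
#' signal. Capture pairs link a subset of regions to genes across tissues,
#' including one-tissue-only contacts that the reproducibility filter must
#' drop.
#'
#' @param cfg `sim_config`.
#' @param sim Result of [simulate_accessibility()].
#' @param gwas Result of [simulate_gwas_panel()].
#' @return List with `genes` (data frame: `gene`, `chrom`, `tss`, `strand`),
#'   `capture` (data frame: `chrom`, `start`, `end`, `gene`, `tissue`), and
#'   `truth$core_genes`.
#' @export
simulate_genes <- function(cfg, sim, gwas) {
  set.seed(cfg$seed + 41L)
  sizes <- sim$chrom_sizes
  ng <- cfg$n_genes
  chrom <- sample(names(sizes), ng, replace = TRUE)
  tss <- floor(runif(ng) * (sizes[chrom] - 1))
  ids <- paste0("g", seq_len(ng))
  nc <- min(cfg$n_core_genes, ng)
  core <- sample.int(ng, nc)
  pv <- gwas$truth$pleiotropic_variants
  if (length(pv) && nc) {
    # anchor core genes on pleiotropic-variant clusters: a core locus is a
    # locus dense in planted cross-disease signal, not a single variant
    vt <- gwas$variants[gwas$variants$variant %in% pv, , drop = FALSE]
    w2 <- cfg$locus_window / 2
    dens <- vapply(seq_len(nrow(vt)), function(i) {
      sum(vt$chrom == vt$chrom[i] & abs(vt$pos - vt$pos[i]) <= w2)
    }, numeric(1))
    ord <- order(dens, decreasing = TRUE)
    anchors <- integer(0)
    for (i in ord) {  # greedy spacing so anchors mark distinct clusters
      if (!length(anchors) ||
          all(vt$chrom[anchors] != vt$chrom[i] |
                abs(vt$pos[anchors] - vt$pos[i]) > cfg$locus_window)) {
        anchors <- c(anchors, i)
      }
      if (length(anchors) == nc) break
    }
    if (length(anchors) < nc) {
      pool <- setdiff(seq_len(nrow(vt)), anchors)
      if (!length(pool)) pool <- seq_len(nrow(vt))
      anchors <- c(anchors, sample(pool, nc - length(anchors),
                                   replace = nc - length(anchors) >
                                     length(pool)))
    }
    chrom[core] <- vt$chrom[anchors]
    tss[core] <- pmax(0, vt$pos[anchors] +
                        sample(-2000:2000, nc, replace = TRUE))
  }
  genes <- data.frame(gene = ids, chrom = chrom, tss = tss,
                      strand = sample(c("+", "-"), ng, replace = TRUE),
                      stringsAsFactors = FALSE)
  # capture pairs: each selected gene contacts 1-3 regions in 1-4 tissues
  tiss <- paste0("capture_tissue", 1:4)
  linked <- sample.int(ng, min(ng, max(10L, round(ng / 3))))
  cap <- list()
  for (gi in linked) {
    ri <- sample(seq_along(sim$regions), sample(1:3, 1))
    for (r in ri) {
      nt <- sample(1:4, 1)
      for (tt in sample(tiss, nt)) {
        cap[[length(cap) + 1]] <- data.frame(
          chrom = as.character(GenomicRanges::seqnames(sim$regions))[r],
          start = GenomicRanges::start(sim$regions)[r] - 1L,
          end = GenomicRanges::end(sim$regions)[r],
          gene = ids[gi], tissue = tt, stringsAsFactors = FALSE)
      }
    }
  }
  list(genes = genes, capture = do.call(rbind, cap),
       truth = list(core_genes = ids[core]))
}

#' Simulate expression counts with planted consistent stage shifts
#'
#' Negative-binomial gene expression over the same sample sheet as the
#' accessibility simulation: planted adult-up/fetal-up genes shift
#' coherently in every tissue, planted antagonistic genes shift in opposite
#' directions across tissues (and must be excluded by the consistency
#' caller), and planted age genes shift between young and old adults.
#'
#' @param cfg `sim_config`.
#' @param meta Sample sheet from [simulate_accessibility()].
#' @param n_genes Number of genes (default `cfg$n_genes`).
#' @param frac_shifted Fraction of genes planted adult-up (and the same
#'   fetal-up; default 0.1).
#' @param frac_antagonistic Fraction planted antagonistic (default 0.05).
#' @param frac_age Fraction planted with a young/old shift (default 0.1).
#' @param logfc Planted magnitude (default 2).
#' @return List with `counts`, `truth` (lists of gene ids: `adult_up`,
#'   `fetal_up`, `antagonistic`, `age_up`).
#' @export
simulate_expression <- function(cfg, meta, n_genes = cfg$n_genes,
                                frac_shifted = 0.1,
                                frac_antagonistic = 0.05, frac_age = 0.1,
                                logfc = 2) {
  set.seed(cfg$seed + 57L)
  ids <- paste0("g", seq_len(n_genes))
  n_sh <- round(n_genes * frac_shifted)
  n_an <- round(n_genes * frac_antagonistic)
  n_ag <- round(n_genes * frac_age)
  pick <- sample.int(n_genes, 2 * n_sh + n_an + n_ag)
  adult_up <- pick[seq_len(n_sh)]
  fetal_up <- pick[n_sh + seq_len(n_sh)]
  antag <- pick[2 * n_sh + seq_len(n_an)]
  age_up <- pick[2 * n_sh + n_an + seq_len(n_ag)]

  tissues <- unique(meta$tissue)
  base <- rnorm(n_genes, 7, 1)
  is_adult <- as.numeric(meta$stage == "adult")
  is_old <- as.numeric(!is.na(meta$age) & meta$age >= 50)
  beta <- rep(0, n_genes)
  beta[adult_up] <- logfc
  beta[fetal_up] <- -logfc
  gamma <- rep(0, n_genes)
  gamma[age_up] <- logfc
  log2mu <- outer(base, rep(1, nrow(meta))) +
    outer(beta, is_adult - 0.5) +
    outer(gamma, ifelse(is_adult == 1, is_old - 0.5, 0))
  # antagonistic genes: sign of the stage shift flips across tissues
  for (g in antag) {
    sgn <- stats::setNames(sample(c(-1, 1), length(tissues), replace = TRUE),
                           tissues)
    if (length(unique(sgn)) == 1) sgn[1] <- -sgn[1]
    log2mu[g, ] <- base[g] + sgn[meta$tissue] * logfc * (is_adult - 0.5)
  }
  mu <- 2^log2mu
  counts <- matrix(rnbinom(length(mu), mu = mu, size = 1 / cfg$dispersion),
                   nrow = n_genes, dimnames = list(ids, meta$sample_id))
  list(counts = counts,
       truth = list(adult_up = ids[adult_up], fetal_up = ids[fetal_up],
                    antagonistic = ids[antag], age_up = ids[age_up]))
}

#' Run the full generator
#'
#' Convenience wrapper producing every pipeline input in one call.
#'
#' @param cfg `sim_config`.
#' @return List with `acc` ([simulate_accessibility()]), `gwas` (with track
#'   annotations merged into `gwas$variants`), `tracks`, `genes`, `expr`,
#'   `peaks`, and a consolidated `truth` list.
#' @export
simulate_all <- function(cfg) {
  acc <- simulate_accessibility(cfg)
  gwas <- simulate_gwas_panel(cfg, acc)
  tracks <- simulate_tracks(cfg, acc, gwas$variants)
  gwas$variants <- tracks$variants
  genes <- simulate_genes(cfg, acc, gwas)
  expr <- simulate_expression(cfg, acc$meta)
  peaks <- simulate_peak_calls(cfg, acc$regions, acc$meta)
  list(acc = acc, gwas = gwas, tracks = tracks, genes = genes, expr = expr,
       peaks = peaks,
       truth = c(acc$truth, gwas$truth, genes$truth,
                 list(expression = expr$truth)))
}

#' Write a simulation to disk in the pipeline's file dialects
#'
#' Emits BED region/element files, TSV count matrices and sample sheets, the
#' variant table, one TSV per disease, gene annotations, capture pairs,
#' chrom.sizes, the conservation track, and a YAML ground-truth sidecar.
#'
#' @param sim Result of [simulate_all()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(x, f, rn = FALSE)
    utils::write.table(x, file.path(dir, f), sep = "\t", quote = FALSE,
                       row.names = rn, col.names = if (rn) NA else TRUE)
  write_chrom_sizes(sim$acc$chrom_sizes, file.path(dir, "genome.chrom.sizes"))
  write_bed(sim$acc$regions, file.path(dir, "regions.bed"))
  tsv(sim$acc$counts, "counts.tsv", rn = TRUE)
  tsv(sim$acc$meta, "samples.tsv")
  tsv(sim$gwas$variants, "variants.tsv")
  dir.create(file.path(dir, "gwas"), showWarnings = FALSE)
  for (ds in names(sim$gwas$panel))
    tsv(sim$gwas$panel[[ds]], file.path("gwas", paste0(ds, ".tsv")))
  tsv(data.frame(disease = names(sim$gwas$panel),
                 file = file.path("gwas", paste0(names(sim$gwas$panel),
                                                 ".tsv")),
                 category = "aging"), "gwas_manifest.tsv")
  tsv(sim$tracks$track, "conservation.tsv")
  write_bed(sim$tracks$conserved, file.path(dir, "conserved_elements.bed"))
  tsv(sim$genes$genes, "genes.tsv")
  tsv(sim$genes$capture, "capture_pairs.tsv")
  tsv(sim$expr$counts, "expression.tsv", rn = TRUE)
  if (!is.null(sim$peaks)) {
    dir.create(file.path(dir, "peaks"), showWarnings = FALSE)
    for (id in names(sim$peaks))
      write_bed(sim$peaks[[id]], file.path(dir, "peaks", paste0(id, ".bed")))
  }
  truth <- list(region_labels = as.list(sim$truth$region_labels),
                nested_age_labels = as.list(sim$truth$nested_age_labels),
                pleiotropic_variants = sim$truth$pleiotropic_variants,
                core_genes = sim$truth$core_genes,
                expression = sim$truth$expression)
  yaml::write_yaml(truth, file.path(dir, "ground_truth.yaml"))
  invisible(dir)
}
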