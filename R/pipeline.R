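## ---------------------------------------------------------------------------
## Config-driven orchestration: read inputs (or simulate them), run the
## stages in dependency order, write TSV/BED outputs stamped with the config
## hash and seed, and assemble a recovery report when ground truth is
## available.
## ---------------------------------------------------------------------------

# Polynomial rolling hash (mod 2^31 - 1) of the serialized config;
# provenance stamp for outputs.
config_hash <- function(cfg) {
  txt <- yaml::as.yaml(cfg)
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Default pipeline configuration
#'
#' Every knob the pipeline exposes, with its default: FDR cutoff 0.05 for all
#' set calling, common-variant MAF threshold 0.05, adult age split at 50
#' years, peak replicate support 2, capture reproducibility across 2 tissues,
#' promoter pad 1 kb, proximity window 10 kb, strong-variant threshold 1e-5,
#' gene locus half-width 100 kb, 100 permutations for enrichment and 999 for
#' gene-set tests.
#'
#' @param ... Overrides merged over the defaults (including a nested
#'   `simulate` list of [sim_config()] arguments).
#' @return Config list.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 1L,
    fdr_cut = 0.05,
    maf_cut = 0.05,
    age_split = 50,
    min_support = 2L,
    capture_min_tissues = 2L,
    promoter_pad = 1000,
    proximity_window = 10000,
    p_strong = 1e-5,
    locus_window = 1e5,
    n_perm_enrich = 100L,
    n_perm_geneset = 999L,
    stages = list(consolidate = TRUE, diffacc = TRUE, nested_age = TRUE,
                  evo = TRUE, gwas = TRUE, generank = TRUE,
                  expression = TRUE, report = TRUE),
    simulate = list()
  )
  ov <- list(...)
  for (nm in names(ov)) {
    if (nm == "stages" || nm == "simulate") {
      for (k in names(ov[[nm]])) cfg[[nm]][[k]] <- ov[[nm]][[k]]
    } else cfg[[nm]] <- ov[[nm]]
  }
  cfg
}

#' Read a pipeline config from YAML
#' @param path YAML file.
#' @return Config list merged over [default_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("missing config file: ", path)
  do.call(default_config, yaml::read_yaml(path))
}

#' Read a simulation directory back into pipeline inputs
#'
#' Mirrors [write_simulation()].
#'
#' @param dir Directory written by [write_simulation()].
#' @return List shaped like the output of [simulate_all()] (without `cfg`;
#'   `truth` present only when the ground-truth sidecar exists).
#' @export
read_simulation <- function(dir) {
  rd <- function(f, rn = FALSE) {
    if (rn) {
      as.matrix(utils::read.table(file.path(dir, f), sep = "\t",
                                  header = TRUE, row.names = 1,
                                  comment.char = "#", check.names = FALSE))
    } else {
      utils::read.table(file.path(dir, f), sep = "\t", header = TRUE,
                        stringsAsFactors = FALSE, comment.char = "#")
    }
  }
  if (!file.exists(file.path(dir, "counts.tsv")))
    stop("missing input: ", file.path(dir, "counts.tsv"))
  chrom_sizes <- read_chrom_sizes(file.path(dir, "genome.chrom.sizes"))
  meta <- rd("samples.tsv")
  manifest <- rd("gwas_manifest.tsv")
  panel <- lapply(stats::setNames(manifest$file, manifest$disease),
                  function(f) rd(f))
  peaks <- NULL
  pk_dir <- file.path(dir, "peaks")
  if (dir.exists(pk_dir)) {
    fs <- list.files(pk_dir, pattern = "\\.bed$", full.names = TRUE)
    peaks <- stats::setNames(lapply(fs, read_bed),
                             sub("\\.bed$", "", basename(fs)))
  }
  truth <- NULL
  ty <- file.path(dir, "ground_truth.yaml")
  if (file.exists(ty)) {
    truth <- yaml::read_yaml(ty)
    truth$region_labels <- unlist(truth$region_labels)
    truth$nested_age_labels <- unlist(truth$nested_age_labels)
  }
  list(acc = list(counts = rd("counts.tsv", rn = TRUE), meta = meta,
                  regions = read_bed(file.path(dir, "regions.bed")),
                  chrom_sizes = chrom_sizes),
       gwas = list(variants = rd("variants.tsv"), panel = panel),
       tracks = list(track = rd("conservation.tsv"),
                     conserved = read_bed(
                       file.path(dir, "conserved_elements.bed"),
                       label = "conserved_element")),
       genes = list(genes = rd("genes.tsv"), capture = rd("capture_pairs.tsv")),
       expr = list(counts = rd("expression.tsv", rn = TRUE)),
       peaks = peaks,
       truth = truth)
}

stamp_tsv <- function(x, path, hash, seed, rn = FALSE) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# epicontext config_hash=%s seed=%d", hash, seed), con)
  suppressWarnings(
    utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = rn,
                       col.names = TRUE))
}

#' Run the full pipeline
#'
#' Executes the stages in dependency order (simulate -> consolidate ->
#' differential accessibility -> nested age -> evolutionary characterization
#' -> GWAS -> gene ranking -> expression -> report), honoring stage toggles.
#' All outputs carry a header comment with the config hash and seed; per-stage
#' counts are logged via `message()`.
#'
#' @param config Config list ([default_config()]) or path to a YAML file.
#' @param out_dir Results directory (created).
#' @param sim Optional pre-built simulation ([simulate_all()] output); when
#'   absent and `config$simulate` is non-empty the generator runs, otherwise
#'   inputs are read from `config$input_dir`.
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list of in-memory stage results (including `report`).
#' @export
run_pipeline <- function(config, out_dir, sim = NULL, quiet = FALSE) {
  cfg <- if (is.character(config)) read_config(config) else config
  hash <- config_hash(cfg)
  seed <- as.integer(cfg$seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[epicontext] ", ...)
  res <- list(config = cfg, hash = hash)

  if (is.null(sim)) {
    if (length(cfg$simulate)) {
      sim_args <- cfg$simulate
      if (is.null(sim_args$locus_window))
        sim_args$locus_window <- cfg$locus_window
      if (is.null(sim_args$proximity_window))
        sim_args$proximity_window <- cfg$proximity_window
      scfg <- do.call(sim_config, c(sim_args, list(seed = seed)))
      say("simulate: ", scfg$n_regions, " regions, ", scfg$n_variants,
          " variants, ", scfg$n_diseases, " diseases")
      sim <- simulate_all(scfg)
    } else {
      if (is.null(cfg$input_dir)) stop("config needs `simulate` or `input_dir`")
      sim <- read_simulation(cfg$input_dir)
    }
  }
  res$sim <- sim
  counts <- sim$acc$counts
  meta <- sim$acc$meta
  regions <- sim$acc$regions
  chrom_sizes <- sim$acc$chrom_sizes

  if (isTRUE(cfg$stages$consolidate) && !is.null(sim$peaks)) {
    consolidated <- consolidate_peaks(sim$peaks, meta,
                                      min_support = cfg$min_support)
    say("consolidate: ", length(consolidated), " reproducible regions")
    write_bed(consolidated, file.path(out_dir, "consolidated.bed"),
              header = sprintf("config_hash=%s seed=%d", hash, seed))
    res$consolidated <- consolidated
  }

  sets <- NULL
  if (isTRUE(cfg$stages$diffacc)) {
    nc <- normalize_counts(counts)
    fit <- moderated_fit(nc$logcpm, stage_design(meta), coef = 2)
    sets <- call_stage_sets(fit, regions, fdr_cut = cfg$fdr_cut)
    say("diffacc: ", length(sets$adult_biased), " adult-biased, ",
        length(sets$fetal_biased), " fetal-biased regions")
    stamp_tsv(fit[, c("region", "log2fc", "moderated_t", "p", "fdr")],
              file.path(out_dir, "diffacc_results.tsv"), hash, seed)
    write_bed(sets$adult_biased, file.path(out_dir, "adult_biased.bed"))
    write_bed(sets$fetal_biased, file.path(out_dir, "fetal_biased.bed"))
    res$diffacc <- fit
    res$sets <- sets
    res$logcpm <- nc$logcpm
  }

  if (isTRUE(cfg$stages$nested_age) && !is.null(sets)) {
    dev_idx <- which(sets$sig)
    if (length(dev_idx) >= 2) {
      nag <- nested_age_contrast(res$logcpm, meta, dev_idx,
                                 age_split = cfg$age_split)
      age_sets <- call_stage_sets(nag$results, regions[dev_idx],
                                  fdr_cut = cfg$fdr_cut,
                                  labels = c("old_biased", "young_biased"))
      both <- which(age_sets$sig)
      dirt <- directionality_test(res$diffacc$direction[dev_idx][both],
                                  nag$results$direction[both])
      say("nested_age: ", length(age_sets$old_biased), " old-biased, ",
          length(age_sets$young_biased), " young-biased; directionality p = ",
          signif(dirt$p, 3))
      stamp_tsv(nag$results[, c("region", "log2fc", "moderated_t", "p",
                                "fdr")],
                file.path(out_dir, "nested_age_results.tsv"), hash, seed)
      write_bed(age_sets$old_biased, file.path(out_dir, "old_biased.bed"))
      write_bed(age_sets$young_biased, file.path(out_dir, "young_biased.bed"))
      res$nested_age <- nag
      res$age_sets <- age_sets
      res$directionality <- dirt
    }
  }

  region_sets <- list()
  if (!is.null(sets)) {
    region_sets <- list(adult_biased = sets$adult_biased,
                        fetal_biased = sets$fetal_biased)
    unalt <- regions[!sets$sig]
    region_sets$unaltered <- region_set(unalt, "unaltered")
  }

  if (isTRUE(cfg$stages$evo) && length(region_sets) &&
      !is.null(sim$tracks)) {
    cons_means <- region_conservation(regions, sim$tracks$track)
    cmp <- NULL
    if (!is.null(sets) && length(sets$adult_biased) >= 2 &&
        length(sets$fetal_biased) >= 2) {
      ai <- which(sets$sig & res$diffacc$log2fc > 0)
      fi <- which(sets$sig & res$diffacc$log2fc < 0)
      cmp <- compare_sets(cons_means$mean_score[fi], cons_means$mean_score[ai])
      say("evo: fetal vs adult conservation p = ", signif(cmp$p, 3),
          ", effect = ", round(cmp$effect, 3))
    }
    enr <- do.call(rbind, lapply(names(region_sets), function(lb) {
      feature_enrichment(region_sets[[lb]], sim$tracks$conserved,
                         chrom_sizes, n_perm = cfg$n_perm_enrich,
                         seed = seed + 101L)
    }))
    stamp_tsv(enr, file.path(out_dir, "evo_enrichment.tsv"), hash, seed)
    vd <- lapply(region_sets, variant_density, variants = sim$gwas$variants,
                 chrom_sizes = chrom_sizes, maf_cut = cfg$maf_cut,
                 n_perm = cfg$n_perm_enrich, seed = seed + 103L)
    res$evo <- list(conservation = cons_means, fetal_vs_adult = cmp,
                    enrichment = enr, variant_density = vd)
  }

  if (isTRUE(cfg$stages$gwas)) {
    pmat <- sapply(sim$gwas$panel, function(d) d$p)
    rownames(pmat) <- sim$gwas$panel[[1]]$variant
    scores <- cross_set_metric(pmat)
    say("gwas: ", sum(!is.na(scores$z_cross)), " variants scored across ",
        ncol(pmat), " diseases")
    stamp_tsv(scores, file.path(out_dir, "cross_set_scores.tsv"), hash, seed)
    res$scores <- scores
    if (length(region_sets)) {
      grp <- nearest_set_label(sim$gwas$variants$chrom,
                               sim$gwas$variants$pos, region_sets,
                               window = cfg$proximity_window)
      res$groups <- grp
      res$group_contrast <- group_contrast(scores, grp)
      enr <- per_disease_enrichment(sim$gwas$panel, sim$gwas$variants,
                                    region_sets$adult_biased,
                                    p_strong = cfg$p_strong,
                                    window = cfg$proximity_window)
      stamp_tsv(enr, file.path(out_dir, "per_disease_enrichment.tsv"),
                hash, seed)
      res$per_disease <- enr
    }
  }

  if (isTRUE(cfg$stages$generank) && !is.null(sim$genes)) {
    capture <- filter_capture(sim$genes$capture,
                              min_tissues = cfg$capture_min_tissues)
    loci <- gene_loci(sim$genes$genes, window = cfg$locus_window,
                      linked = capture)
    gs <- gene_scores(sim$gwas$panel, sim$gwas$variants, loci)
    ranks <- aggregate_ranks(gs$scores)
    say("generank: ", nrow(ranks), " genes ranked across ",
        ncol(gs$scores), " diseases")
    stamp_tsv(ranks, file.path(out_dir, "gene_ranks.tsv"), hash, seed)
    res$capture <- capture
    res$gene_ranks <- ranks
    res$gene_scores <- gs
  }

  if (isTRUE(cfg$stages$expression) && !is.null(sim$expr)) {
    cs <- consistency_shift(sim$expr$counts, meta)
    say("expression: ", length(cs$adult_up), " adult-up, ",
        length(cs$fetal_up), " fetal-up genes")
    res$expression <- cs
    if (!is.null(sim$genes) && !is.null(res$capture) && !is.null(sets)) {
      prom <- promoter_windows(sim$genes$genes, pad = cfg$promoter_pad)
      reg_genes <- regions_to_genes(sets$adult_biased, res$capture, prom)
      if (length(reg_genes) && length(cs$adult_up)) {
        res$expr_overlap <- set_overlap_test(reg_genes, cs$adult_up,
                                             sim$genes$genes$gene)
      }
    }
  }

  if (isTRUE(cfg$stages$report) && !is.null(sim$truth)) {
    res$report <- recovery_report(res, sim$truth)
    yaml::write_yaml(res$report, file.path(out_dir, "recovery_report.yaml"))
    say("report: sensitivity = ", round(res$report$diffacc_sensitivity, 3),
        ", empirical FDR = ", round(res$report$diffacc_fdr, 3))
  }
  invisible(res)
}

#' Compare pipeline calls to planted ground truth
#'
#' @param res Result list from [run_pipeline()].
#' @param truth Ground-truth list from the generator.
#' @return Named list of recovery metrics (sensitivity and empirical FDR of
#'   the developmental calls, pleiotropic-variant top-decile fraction, core
#'   gene-set permutation p, directionality-test p).
#' @export
recovery_report <- function(res, truth) {
  out <- list()
  if (!is.null(res$diffacc) && !is.null(truth$region_labels)) {
    lab <- truth$region_labels[res$diffacc$region]
    called <- res$sets$sig
    dir_ok <- (res$diffacc$log2fc > 0 & lab == "adult") |
      (res$diffacc$log2fc < 0 & lab == "fetal")
    tp <- called & lab != "null" & dir_ok
    out$diffacc_sensitivity <- sum(tp) / sum(lab != "null")
    out$diffacc_fdr <- if (sum(called)) sum(called & lab == "null") /
      sum(called) else 0
  }
  if (!is.null(res$scores) && !is.null(truth$pleiotropic_variants)) {
    z <- res$scores$z_cross
    thr <- stats::quantile(z, 0.9, na.rm = TRUE)
    pl <- res$scores$variant %in% truth$pleiotropic_variants
    if (any(pl))
      out$pleiotropic_top_decile <- mean(z[pl] >= thr, na.rm = TRUE)
  }
  if (!is.null(res$gene_ranks) && length(truth$core_genes)) {
    gst <- gene_set_test(res$gene_ranks,
                         intersect(truth$core_genes, res$gene_ranks$gene),
                         n_perm = 999, seed = res$config$seed + 211L)
    out$core_gene_set_p <- gst$p
  }
  if (!is.null(res$directionality)) out$directionality_p <- res$directionality$p
  out
}
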