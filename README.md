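# epicontext

Chromatin accessibility is not static: regions open or close as tissues
develop from fetal to adult forms, and again across adulthood. A regulatory
variant therefore acts under a *shifting epigenetic context*, and that
context plausibly modulates both the selective pressure on its sequence and
its contribution to heritable disease risk. `epicontext` is an R package
for studying exactly this: it calls stage-biased open-chromatin region sets
from accessibility count matrices, characterizes their sequence evolution
against randomized genomic backgrounds, aggregates GWAS evidence per
variant across many diseases, and prioritizes gene loci by cross-disease
rank aggregation — with a synthetic-data generator that plants recoverable
ground truth through every stage.

## The statistics at the core

* **Moderated differential accessibility.** Per-region least squares on
  log2-CPM with an empirical-Bayes variance prior:
  `s2_post = (d0*s02 + d*s2)/(d0 + d)`, moderated t on `d0 + d` df, prior
  `(d0, s02)` by moment-matching the scaled-F distribution of sample
  variances. Stage sets are called at BH FDR < 0.05 and partitioned by
  fold-change sign (adult-biased / fetal-biased); a nested young/old
  contrast (age split at 50) runs the same engine inside the
  developmentally-altered regions, and a 1-df chi-square tests whether the
  two contrasts share direction.
* **Per-bp permutation enrichment.** Observed overlap per bp of a target
  set versus length- and chromosome-preserving uniform randomizations,
  with empirical p-values whose floor is `1/(n_perm+1)`.
* **Cross-disease variant score.** Unsigned per-disease evidence
  `z_i = qnorm(1 - p_i/2)` summed Stouffer-style and standardized by the
  moments of |N(0,1)| (`E0 = sqrt(2/pi)`, `SD0 = sqrt(1 - 2/pi)`), so the
  global null is exactly mean 0, sd 1. Strong-variant enrichment near
  region sets is an exact hypergeometric tail per disease, BH across
  diseases, signed by direction.
* **Gene-locus prioritization.** Per disease, a gene scores the minimum p
  over SNPs in its TSS window (default ±100 kb) unioned with reproducible
  promoter-capture contacts (seen in ≥2 tissues); ranks are aggregated by
  geometric mean across diseases and gene sets are tested against
  equal-size random draws.

## Worked example

The bundled demo simulates every input at desk scale (3 chromosomes of
300 kb, 800 regions, 8000 variants, 12 disease panels, 200 genes) and runs
the full pipeline:

```r
library(epicontext)
demo <- system.file("extdata", "demo_config.yaml", package = "epicontext")
res <- run_pipeline(demo, "demo_out")
```

which logs, stage by stage:

```
[epicontext] simulate: 800 regions, 8000 variants, 12 diseases
[epicontext] consolidate: 805 reproducible regions
[epicontext] diffacc: 81 adult-biased, 84 fetal-biased regions
[epicontext] nested_age: 43 old-biased, 47 young-biased; directionality p = 1.42e-07
[epicontext] evo: fetal vs adult conservation p = 4.04e-24, effect = 0.957
[epicontext] gwas: 8000 variants scored across 12 diseases
[epicontext] generank: 200 genes ranked across 12 diseases
[epicontext] expression: 20 adult-up, 20 fetal-up genes
[epicontext] report: sensitivity = 1, empirical FDR = 0.03
```

Reading the output: of 160 planted stage-biased regions the moderated model
recovers every one (sensitivity 1) with 3% false discoveries at the 5% FDR
target; the planted young/old shifts inside them share the developmental
direction, so the chi-square rejects decisively (p = 1.4e-7); fetal-biased
regions carry the planted conservation shift (rank test p = 4e-24 with a
common-language effect size of 0.96); and the ground-truth recovery report

```r
str(res$report)
#> $ diffacc_sensitivity   : num 1
#> $ diffacc_fdr           : num 0.0303
#> $ pleiotropic_top_decile: num 1
#> $ core_gene_set_p       : num 0.014
#> $ directionality_p      : num 1.42e-07
```

confirms that all planted pleiotropic variants land in the top decile of
the cross-disease score and the planted core genes rank significantly
better than random gene sets. Cross-set score means by variant
neighborhood (`res$group_contrast$summary`) show the planted ordering —
variants near adult-biased regions score highest (mean 0.41), fetal-biased
next (0.21), unaltered accessible regions lowest (0.13).

A thin command-line wrapper is included for shell use:

```sh
Rscript inst/scripts/epicontext.R run --config inst/extdata/demo_config.yaml --out demo_out
```

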