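---
title: "Methods: chromatin-accessibility context, constraint, and cross-disease signal"
author: "epicontext"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: chromatin-accessibility context, constraint, and cross-disease signal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epicontext)
```

## The problem this package addresses

Open-chromatin regions change accessibility as tissues develop from their
fetal to adult forms, and again as adults age. A region that is more
accessible in adult tissue ("adult-biased") presents its regulatory
sequence to *trans*-acting machinery under a different epigenetic context
than one whose accessibility is highest in fetal tissue ("fetal-biased"),
and the same applies to the nested young-adult/old-adult split. Regulatory
variants inside or near these regions therefore experience different
selective pressures and contribute differently to heritable disease risk.
`epicontext` implements the full analysis chain needed to study this:

1. call stage-biased region sets from accessibility count matrices
   (`diffacc`),
2. characterize their sequence evolution against randomized genomic
   backgrounds (`evo`),
3. aggregate per-variant GWAS evidence across many diseases and test
   enrichment near region sets (`gwas`),
4. prioritize gene loci by cross-disease rank aggregation (`generank`),
   with promoter-capture gene linking (`gene_links`) and expression
   consistency calls (`expression`) feeding the gene sets.

All stages run end-to-end on synthetic data with planted ground truth, so
every claim the package makes about itself is checkable.

## The moderated differential-accessibility model

Counts are library-size normalized to
$\log_2\!\big((c + 0.5)/(N + 1) \cdot 10^6\big)$ (log2-CPM with pseudocount
0.5). For each region $i$ a linear model is fitted on a design holding an
intercept, an adult-stage indicator, and additive tissue covariates, so the
stage contrast is pan-tissue; per-tissue contrasts run the same engine on
sample subsets. Residual variances $s_i^2$ on $d_i$ degrees of freedom are
shrunk toward an empirical-Bayes prior $(d_0, s_0^2)$:

$$\tilde s_i^2 = \frac{d_0 s_0^2 + d_i s_i^2}{d_0 + d_i},$$

with the moderated $t = \hat\beta_i / (u\,\tilde s_i)$ referred to a
$t$-distribution on $d_0 + d_i$ df. The prior is estimated by
moment-matching the scaled-F distribution of the sample variances on the
log scale (mean and variance of $\log s_i^2$ corrected by digamma/trigamma
terms; `fit_variance_prior()`), with the trigamma inverse solved by Newton
iteration. Two degenerate limits are exact and tested: $d_0 = 0$ returns
the ordinary per-region $t$, and $d_0 \to \infty$ with fixed $s_0^2$
returns the pooled-prior-variance normal statistic. On shared fixtures the
engine agrees with the reference empirical-Bayes implementation in the
`limma` package to $10^{-8}$, which we use strictly as an independent
cross-check.

Stage-biased sets are the regions passing a Benjamini–Hochberg FDR below
0.05, partitioned by fold-change sign (positive adult-vs-fetal log2FC →
adult-biased). The nested age contrast reruns the same engine on adult
samples only, split at 50 years (strictly younger → "young"), restricted
to the developmentally-altered regions and BH-corrected within that
restricted family. The directionality-sharing test cross-tabulates the two
direction labels over doubly-significant regions and applies a Pearson
chi-square on 1 df; the Yates correction is off by default (a flag enables
it) because the convention must be fixed for reproducibility, and a zero
margin is reported as undefined rather than an error.

Precision weights are available (a lowess trend of
$\sqrt{\mathrm{sd}}$ against average log-count, evaluated at fitted
log-counts, weight = inverse fourth power) but default off for
accessibility counts; the young/old expression contrast enables them,
mirroring the weighted count pipelines used for RNA-seq.

## Randomized backgrounds and enrichment

`shuffle_regions()` redraws each interval's start uniformly over all
positions where it fits, preserving its length and chromosome, optionally
rejecting placements in an exclusion mask. Matching on chromosome and
length only is a deliberate choice: it is the randomization the per-bp
overlap figures imply, and richer covariate matching is out of scope.

`feature_enrichment()` reports observed per-bp overlap
(`overlap_bp(target, feature) / total_bp(target)`), the mean of the same
statistic over shuffles (each normalized by its own union size, so a
whole-genome feature gives fold = 1 identically), and permutation
p-values. Two conventions are reported side by side: `empirical_p` is the
smaller one-tail probability $(1 + \#\{\text{null at least as extreme}\})
/ (n_{perm}+1)$, whose floor $1/(n_{perm}+1)$ is attainable; `p_two_sided`
doubles it, capped at 1. Both appear in the output because depletion is as
meaningful as enrichment here and the two summaries answer different
questions.

Common variants are those with MAF ≥ 0.05; variant density is the count of
passing variants inside the target per union bp, compared against the
same shuffled backgrounds and against user-supplied feature sets
(introns, promoter-TSS windows, repeats).

## Cross-disease aggregation

Disease effect signs are incommensurable across traits, so per-disease
evidence is taken unsigned: $z_i = \Phi^{-1}(1 - p_i/2)$, the magnitude of
the z-score behind a two-sided $p$. The cross-set score standardizes the
Stouffer-style sum so the global null is exactly mean 0, sd 1:

$$z_{cross} = \frac{\sum_i z_i - n\,E_0}{\sqrt{n}\,SD_0},
\qquad E_0 = \sqrt{2/\pi},\; SD_0 = \sqrt{1 - 2/\pi},$$

the moments of $|N(0,1)|$. Variants missing from a disease are dropped
from the sum with $n$ adjusted; a variant is scored only when observed in
at least `min_diseases` panels (default: all). A mean $-\log_{10} p$
alternative is exposed in config; defaults are used everywhere the package
tests itself. Zero p-values are clamped to the smallest representable
positive number with a warning.

Per-disease enrichment of strong variants (default threshold $10^{-5}$;
the headline studies' threshold is not printed, so it is a named knob)
near a region set uses the exact hypergeometric tail on the 2×2 of
{strong vs not} × {nearby vs not}, upper tail for enrichment and lower for
depletion, BH across diseases, reported as signed $-\log_{10}$ adjusted p.
"Nearby" is one shared proximity rule everywhere: within the interval
extended by `proximity_window` bp (default 10 kb — the analyses this
mirrors never state their window, so it is a single config knob applied
uniformly).

## Gene-locus prioritization

A gene's locus is a symmetric TSS window (default ±100 kb) optionally
extended — union, never replacement — by promoter-capture interactions
that survive the reproducibility filter (same contact seen in ≥2
tissues/cell types). Per disease, the gene score is the minimum p over
SNPs in the locus; genes with no candidate SNP are flagged and ranked
last, at $n_{ranked} + (n_{nodata}+1)/2$. Ranks (ascending in p, ties by
average) are aggregated by geometric mean, making the aggregate invariant
to any monotone transform of per-disease scores. `gene_set_test()`
compares a gene set's mean aggregate against equal-size uniform draws from
the universe; with the set equal to the universe the p-value is 1 by
construction, and a top-k set attains the permutation floor.

The `cdf_shift_test()` summarizes whether variants in a locus family score
higher than the population: a normal distribution is fitted (mean, sd) to
the baseline scores and the target is tested against that reference CDF
with a one-sample Kolmogorov–Smirnov test, reporting the fold-change of
$-\log_{10} p$ relative to the same test applied to the full baseline.
This is the simplest self-normalizing reading of an under-specified
construction: a location-only z-test would make the baseline-vs-itself
reference exactly $p = 1$ and the fold-change 0/0, whereas the KS version
makes the self-comparison fold-change exactly 1.

## What the generator emulates — and what it does not

`sim_config()` fixes the study conditions once:

| parameter | default | why |
|---|---|---|
| tissues × stages × replicates | 3 × 2 × 4 | the smallest design where a pan-tissue contrast with tissue covariates and a nested young/old split are both estimable with reasonable power |
| `effect_logfc` | 2 | a strong but realistic planted accessibility shift (log2 units) |
| `dispersion` | 0.1 | negative-binomial overdispersion typical of consolidated accessibility counts; the moderated model must absorb it |
| `frac_adult_biased`, `frac_fetal_biased` | 0.1 each | planted class sizes large enough for rank tests downstream |
| `frac_age_shifted`, `frac_share_direction` | 0.5, 0.8 | half the developmentally-altered regions also shift with age, sharing the developmental direction 80% of the time, so the directionality-sharing test is positive by construction |
| `n_diseases` | 20 | desk-scale stand-in for a large panel of age-associated trait GWAS |
| `frac_pleiotropic`, `pleiotropy_strength` | 0.02, 3 | 2% of variants carry expected \|Z\| = 3 in 70% of diseases, signs random per disease (the aggregation is unsigned, so sign mixing is harmless) |
| `conservation_shift` | 0.5 | mean per-bp conservation added inside fetal-biased regions; recovered within its closed-form CI |
| `age_mixing` | 0.5 | allele age anti-correlated with conserved-element membership; 0 switches the association off |

Baseline accessibility is log-normal per region; counts are
negative-binomial with a per-sample library factor. Regions are placed on
an even grid with uniform jitter, which guarantees non-overlap and keeps
placement near-uniform. Adult ages alternate young/old across replicates
so both age groups exist in every tissue. Pleiotropic variants are
relocated near regions of a designated class (adult-biased by default);
minor allele frequencies are log-uniform on [0.005, 0.5], an
approximation to the neutral 1/f frequency spectrum that puts mass on
both sides of the 0.05 common-variant threshold. Core genes are anchored
on *clusters* of pleiotropic variants (greedy selection over local
density with spacing of one locus width): a "core gene" in this model is a
locus dense in planted cross-disease signal, not a locus containing one
moderately-associated SNP — with ~250 null variants per desk-scale locus
window, a single expected-\|Z\|-3 variant is not reliably distinguishable
from the window's best null p, and the planted-recovery property would
hold only in a minority of seeds.

The generator deliberately omits: linkage disequilibrium (every variant is
independent), real genome sequence, chromosome-specific gene density, and
per-tissue batch structure. Passing tests therefore demonstrate that the
statistical machinery recovers planted structure under clean sampling
assumptions; they say nothing about LD-induced correlation of GWAS
evidence, peak-calling artifacts, or covariate confounding in real
consortium data.

## Numerical and scale choices

* **Coordinates.** 0-based half-open in every file (BED dialect,
  tab-separated, no headers); 1-based closed inside R (`GRanges`).
  A promoter is the TSS padded 1 kb both ways: the half-open window
  $(tss-1000,\ tss+1000]$.
* **Desk-scale geometry.** The demo and the self-checks run on synthetic
  genomes of a few hundred kb per chromosome. The locus half-width is
  scaled accordingly (20 kb in the demo config): a ±100 kb window — the
  genome-scale default — would cover a third of a 300 kb chromosome and
  erase locus structure. Problem sizes used by the self-checks: 2000
  regions × 24 samples for planted-region recovery; 10^4 variants × 100
  null diseases for cross-set calibration; 100 null seeds for the
  empirical-FDR bound (the per-seed false-discovery proportion under a
  global null is 0/1, so a wide seed panel is needed to estimate its mean
  with useful precision); 20 seeds each for the directionality and
  pleiotropy-recovery rates.
* **Ties and degenerate inputs.** Rank ties use average ranks; the
  variance-prior fit falls back to $d_0 = \infty$ (pure pooling) when log
  sample variances are no more dispersed than sampling noise; a 2×2 margin
  of zero makes the chi-square undefined-with-reason; conservation-track
  gaps are skipped, never zero-filled, with per-region coverage fractions
  reported; an empirical p is never 0.
* **Determinism.** Every stochastic stage takes a seed; the generator
  derives fixed offsets from `cfg$seed` per stage so each product is
  individually reproducible, and pipeline outputs are stamped with a hash
  of the config and the seed.

## Open choices made here

* Whether precision weights or an unweighted trend fit is the right
  default for accessibility counts is genuinely open; both are
  implemented, weights default off, and the shared engine means the
  expression module can flip the switch without code divergence.
* The replicate-support threshold for reproducible peaks defaults to 2
  within a tissue/stage group, capped at the group size, and is config.
* The capture/promoter/domain linking rules are unioned; a `rules`
  argument restricts to any subset.
* The consistency caller for broad expression shifts (per-tissue log2FC
  with a magnitude threshold, a minimum number of consistent tissues, and
  a veto on any opposite-signed tissue) is this package's documented
  stand-in for an unavailable exact rule; every threshold is exposed.

## Limitations

The moderated engine assumes approximately normal log-CPM residuals;
at very low counts the normal approximation thins out and the voom-style
weights only partially compensate. The permutation backgrounds match
length and chromosome but not GC, mappability, or feature density. The
cross-set metric treats diseases as independent; correlated GWAS panels
(shared controls, genetic correlation) inflate its variance in real data.
Gene linking trusts the supplied capture and domain annotations; it does
not call interactions. None of the numbers in this vignette are claims
about real tissue data — they are properties of the pipeline verified on
its own generator.
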