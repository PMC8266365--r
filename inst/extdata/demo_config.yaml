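# Bundled demo: simulate every input at desk scale and run the full
# pipeline end-to-end, emitting a ground-truth recovery report.
seed: 1
fdr_cut: 0.05
maf_cut: 0.05
age_split: 50
min_support: 2
capture_min_tissues: 2
promoter_pad: 1000
proximity_window: 10000
p_strong: 1.0e-5
# locus half-width scaled to the 300 kb demo chromosomes (the 100 kb
# genome-scale default would cover a third of a chromosome)
locus_window: 20000
n_perm_enrich: 50
n_perm_geneset: 999
simulate:
  n_chrom: 3
  chrom_len: 300000
  n_regions: 800
  n_tissues: 3
  replicates_per_group: 4
  n_variants: 8000
  n_diseases: 12
  n_genes: 200
  n_core_genes: 15
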