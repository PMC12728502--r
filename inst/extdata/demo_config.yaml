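# Demonstration run: simulated six-species cohort with clean genotyping
# (no genotype error) so the planted duplicated gene pair is recovered as
# the unique candidate. Override `outdir` and `seed` as needed.
seed: 3
stages:
  simulate: true
  qc: true
  genotype: true
  scan: true
  load: true
sim:
  chrom_length: 300000
  supergene_interval: [60001, 260000]
  n_sites_background: 60
  n_sites_divergent: 200
  n_genes: 10
  genotype_error_rate: 0
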