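# Example pipeline configuration (paths are relative to where you run it).
genotypes: fixture/genotypes        # PLINK prefix (.bed/.bim/.fam)
pedigree: fixture/pedigree.tsv
ebv:
  type_score: fixture/ebv_type_score.tsv
out_dir: herdgen_out
seed: 1
qc:
  min_maf: 0.01
  hwe_alpha: 0.001
roh:
  window_snps: 15
  min_snps: 40
  min_length: 4.0e6
ne:
  alpha: 2
  recomb_mapping: linear
gwas:
  n_axes: 3
deregress_c: 0.10
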