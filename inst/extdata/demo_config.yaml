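# demo pipeline config: pure simulation, desk-scale
seed: 42
simulate:
  n_genes: 300
  n_replicates: 3
  baseline_mean: 50
  frac_deg: 0.15
  cluster_fraction: 0.6
thresholds:
  fc_min: 2
  q_max: 0.05
  rpkm_min: 1
  dev_fc_min: 2
proximity:
  n_permutations: 200
  statistic: median_nn_distance
enrichment:
  min_term_size: 3
motif: GATAAG
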