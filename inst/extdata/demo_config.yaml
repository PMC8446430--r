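# Demo pipeline configuration: simulate the default three-cohort study on the
# 18-population panel, then run every analysis stage at desk scale.
seed: 1
measure: counts
simulate:
  panel: 18
  n_hiv_pos: 12
  n_hiv_neg: 10
  n_control: 24
analyses: [iindex, cluster, fis, battery, pca]
fis:
  case_cohort: hiv_pos
  subset_size: 7
  n_subsets: 2000
battery:
  decimals: 3
pca:
  measure: proportions
  n_components: 2
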