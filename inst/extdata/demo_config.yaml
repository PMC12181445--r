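# Demo configuration: a small end-to-end run on simulated data.
# Sizes are kept modest so the run completes in well under five minutes
# on a single CPU; scale them up for more faithful study designs.
geneset: "builtin:senskin"
seed: 1
stages: [simulate, score, contrast, cluster, gsea, de]
simulate:
  sc:
    n_genes: 600
    cells_per_type: {Fibroblast: 60, Keratinocyte: 60, TCell: 60, Macrophage: 60}
    conditions: [UVprotected, UVexposed]
    n_samples_per_condition: 3
    effect_delta: 1.0
    down_delta: 1.0
    affected_fraction: 1.0
    nb_dispersion: 0.4
  bulk:
    n_genes: 1200
    conditions: [young, old]
    n_samples_per_condition: 24
    effect_delta: 0.5
    down_delta: 0.5
score:
  scale: 10000
contrast:
  alpha: 0.05
  adjust: bonferroni
cluster:
  k: 5
  skewness_threshold: 2
  log_mode: global
  groupby: [sample_id]
gsea:
  n_perm: 500
de:
  lnfc_cutoff: 0.25
  alpha: 0.05
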