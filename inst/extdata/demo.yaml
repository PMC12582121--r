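# Demo pipeline configuration: all-synthetic inputs, every stage enabled.
seed: 1
synthetic:
  n_genes: 300
  n_guides_per_gene: 4
  depleted_gene_fraction: 0.1
  screen_depth: 500000.0
  screen_fold: 8.0
  nb_dispersion: 0.05
  stabilization_lfc: -0.5
  te_lfc: 0.0
  utr5_enrichment: 0.5
  n_sites_per_sample: 500
stages:
  screen: yes
  clip: yes
  de: yes
  te: yes
  cdf: yes
  assays: yes
thresholds:
  fold_threshold: 5.0
  primary_delta: 1.0
  secondary_delta: 2.5
  merge_gap: 50
  solo_width: 50
  n_bins: 50
  pseudocount: 0.5
  control_set_size: 100
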