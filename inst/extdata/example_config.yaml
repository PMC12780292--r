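# Example pipeline configuration: a small synthetic cohort with one
# disease group, suitable for a quick end-to-end run.
cohort:
  n_reference: 60
  n_disease:
    Diabetes mellitus: 20
  noise_sd: 0.5
  seed: 42
atlas:
  variance_fraction: 0.90
  max_components: 25
  alignment: consensus
qc:
  mahalanobis_alpha: 0.001
  projection_mad_mult: 5
  volume_rel_tol: 0.20
metrics:
  density: 1.05
  afterload_variant: product
discrimination:
  folds: 5
  seed: 1
  vif_threshold: 5
out_dir: bivatlas_out
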