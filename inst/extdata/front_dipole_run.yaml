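# Example pipeline configuration: one tidal-mixing-front transect and
# one upwelling-downwelling dipole transect at 40 x 400 cells, with the
# default plankton patch set.
seed: 1
sensitivity_n: 1024
downsample_factor: 4
training:
  epochs: 50
  n_train: 25000
scenarios:
  - type: front
  - type: dipole
patches:
  - group: pluteus
    habitat_label: 2
    mean_density: 12
    zero_inflation: 0.3
    lognormal_sigma: 0.8
  - group: copepoda
    habitat_label: 0
    mean_density: 8
    zero_inflation: 0.4
  - group: appendicularia
    habitat_label: 3
    mean_density: 5
    zero_inflation: 0.5
association:
  n_randomizations: 100
  alpha: 0.01
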