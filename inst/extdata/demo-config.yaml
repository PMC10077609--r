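# Demo pipeline configuration: a synthetic region at the study scale.
seed: 42
n_sites: 702
n_nodes: 1500
sampler_n: 10000
density_cutpoints: [100, 1000]
fertility_cutpoints: [1.3, 1.6]
time_thresholds: [30, 40]
target_closure_rate: 0.1026
scenarios:
  - name: all
  - name: pediatrics_only
    require_pediatrics: true
  - name: min600_births
    min_live_births: 600
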