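# Example drspipe run configuration. Fields omitted here keep the
# defaults of default_run_config().
seed: 7
probes: [short_SDD, long_SDD]
grid_step: 5
contrast: default
n_patients: 47
sites_per_patient: 15
alpha: 0.001
min_run: 3
max_gap: 0
k_components: 4
k_nn: 10
iterations: 20
leakage_free: false
band_sets:
  hemoglobin Q-band:
    - [530, 590]
  optical window:
    - [600, 1230]
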