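# Demo pipeline configuration: small cohort, sensor-level end to end.
seed: 7
out_dir: megconn_demo
cohort:
  n_mtbi: 8
  n_control: 8
  sampling_rate: 200
  duration: 60
  n_seeds: 20
  bands: [delta, theta]
  effects: default
sensor:
  enabled: true
  dipole_moment: 1.0e-8
  noise_sd: 30
  artifacts: true
preprocess:
  f_lo: 1
  f_hi: 90
  notch: [60]
  epoch_length: 10
  motion_threshold: 10
  jump_threshold: 2000
analysis:
  bands: [delta]
  orthogonalize: true
stats:
  n_perm: 500
  q: 0.05
ml:
  bands: [delta]
  n_perm: 50
  k: 8
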