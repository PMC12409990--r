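# Demo pipeline configuration: a small synthetic ensemble with two planted
# modes, a coarse-grained contact cutoff suited to the C-alpha + sidechain
# stub geometry, and a three-state unfolding experiment from the "21M"
# preset. Runs end-to-end in well under five minutes on one CPU.
seed: 7
out_dir: demo_out
ensemble:
  n_residues: 24
  n_frames: 80
  mode_sds: [2.0, 1.0]
  isotropic_noise_sd: 0.05
rin:
  cutoff: 6.0
  dc_threshold: 20
  bc_threshold: 1000
fel:
  fit_selection: CA
  pca_selection: heavy
  bins: 24
foldfit:
  preset: 21M
  model: three_state
  n_starts: 10
  urea_points: 25
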