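# coroflow run configuration. Every key is optional; unset keys take the
# defaults shown here. Unknown keys are rejected.
seed: 1

simulate:
  n_cases: 12
  split: [8, 2, 2]          # ordered train/val/test counts
  n_levels: 3               # binary tree depth (2^n - 1 branches)
  root_radius: [1.6, 2.0]   # mm, sampled per case
  root_length: [22, 26]     # mm
  bend_amplitude: [0.5, 1.5]  # mm
  n_stenoses: [1, 2]
  severity: [0.35, 0.75]    # fractional radius reduction
  extent: [3, 6]            # mm
  position: [0.2, 0.8]      # fraction along the branch
  point_spacing: 0.75       # mm between centerline samples
  spacing: 0.5              # voxel size, mm
  noise_sd: 20              # intensity noise (abstract units)
  lumen_intensity: 400
  background_intensity: 0
  cloud_density: 5          # pressure samples per mm of centerline
  cloud_jitter_sd: 0.3      # mm
  inlet_pressure: 100       # mmHg (13,330 Pa equivalent)
  viscosity: 0.04           # g/(cm s)
  outlet_resistance: 1333   # Pa s/cm^3 per terminal branch

dataset:
  patch_size: 28            # voxels per edge
  radius_mm: 5              # pressure-label averaging radius
  intensity_window: [0, 500]

train:
  models: [icd, mlp]
  learning_rate: 1.0e-5
  weight_decay: 1.0e-3
  batch_size: 100
  epochs: 100
  huber_delta: 1
  T: 1000                   # diffusion steps
  beta_start: 1.0e-4
  beta_end: 0.02
  channels: [8, 16, 32]     # encoder widths
  hidden_dim: 128
  coord_emb_dim: 3
  n_chains: 10              # reverse chains averaged at inference

evaluate:
  ffr_threshold: 0.80
  export_vtk: false
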