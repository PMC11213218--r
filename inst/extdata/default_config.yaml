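# pnmsDCE pipeline configuration (defaults shown; any field may be omitted).
# Every stochastic stage derives its own stream from the single global seed.

paths:
  output_dir: pnms_out        # artifact tree root

grid:                         # acquisition time grid
  n_frames: 400               # dynamic frames
  spacing_s: 1.55             # frame spacing (seconds)
  injection_time_s: 60        # bolus arrival after scan start (seconds)
  exclude_frames: 20          # initial frames dropped from analysis (~30 s)

aif:                          # simulated population arterial input function
  peak: 3.0                   # peak delta-R1 (1/s)
  alpha: 3.0                  # gamma-variate shape
  time_to_peak_s: 12          # first-pass time to peak (s)
  recirc_fraction: 0.3        # recirculation plateau, fraction of peak
  recirc_rise_s: 30           # recirculation rise constant (s)
  washout_tau_s: 300          # washout constant (s)

phantom:                      # synthetic study geometry and kinetics
  dim: [32, 32, 3]            # voxels (x, y, slices)
  core_radius: 5              # Model-2 tumor core disc radius (voxels)
  rim_radius: 8               # Model-3 rim outer radius (voxels)
  vp_range: [0.01, 0.04]      # plasma volume fraction
  ktrans_range: [0.05, 0.3]   # forward transfer constant (1/min)
  kep_range: [0.5, 2.5]       # reverse transfer constant (1/min)
  noise_sd: 0.05              # Gaussian noise SD relative to peak (SNR 20)

cohort:
  n_animals: 12               # phantom subjects

nms:
  confidence_level: 0.95      # F-test confidence level
  kep_bounds: [0.001, 5]      # Kep search interval (1/min)

som:                          # Kohonen map hyperparameters
  rows: 8
  cols: 8
  initial_radius: 3           # initial hexagonal neighborhood radius
  ordering_steps: 100         # ordering-phase ("cover step") epochs
  max_epochs: 250             # maximum batch epochs
  init: linear                # linear (deterministic) or random

pnms:
  tau: 0.5                    # probability threshold for region maps
  kep_floor: 0.001            # smallest usable Kep for ve (1/min)

cv:                           # nested cross-validation
  k: 3                        # folds (10 at full cohort scale)
  train_fraction: 0.66
  n_boot: 10000               # bootstrap resamples for fold CIs

seed: 1
log_level: info               # info | quiet
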