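# Demo experiment: 20-cell healthy-like retina, 5 minutes of visual white
# noise, LN fits, noise-ratio estimation and a flash-count decoding scan.
# Run with: runPipeline(system.file("extdata", "demo_config.yaml",
#                                   package = "retfidelity"), outDir = "out")
experiment: demo
seed: 1
stages: [stim, simulate, sta, fit, noise, decode]
stimulus:
  frames: 9000
  height: 20
  width: 20
  frame_rate: 30
  p_bright: 0.5
  pixel_pitch: 60
  modality: visual
population:
  preset: demo
  n_cells: 20
  noise_ratio: 0.2
fit:
  model: ln
  max_cells: 5
noise:
  nr_grid: [0, 0.2, 0.4, 0.6, 0.8, 1]
  n_seeds: 2
decode:
  axis: n_flashes
  grid: [1, 2, 4]
  n_trials: 500
  c_size_px: 14
  k: 200
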