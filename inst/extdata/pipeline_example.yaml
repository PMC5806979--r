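# Example pipeline configuration (standard measurement settings:
# 5 x 5 grid, 12 components, rest frame 1, 30 frames at 30 fps)
out_dir: velogrid_out
seed: 7
n: 5
k: 12
rest_frame: 1
scene:
  z0: 40
  amplitude: 4.7
  n_frames: 30
render:
  noise_sd: 2
match:
  max_disparity: 96
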