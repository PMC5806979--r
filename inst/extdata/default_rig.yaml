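left:
  f: 4.0
  kappa1: 0.002
  cx: 160.0
  cy: 120.0
  sx: 1.0
  dx: 0.01
  dy: 0.01
  width: 320
  height: 240
  R:
  - 1.0
  - 0.0
  - 0.0
  - 0.0
  - 1.0
  - 0.0
  - 0.0
  - 0.0
  - 1.0
  T:
  - 0.0
  - 0.0
  - 0.0
right:
  f: 4.0
  kappa1: 0.002
  cx: 160.0
  cy: 120.0
  sx: 1.0
  dx: 0.01
  dy: 0.01
  width: 320
  height: 240
  R:
  - 1.0
  - 0.0
  - 0.0
  - 0.0
  - 1.0
  - 0.0
  - 0.0
  - 0.0
  - 1.0
  T:
  - -8.0
  - 0.0
  - 0.0
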