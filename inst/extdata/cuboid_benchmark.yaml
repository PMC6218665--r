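geometry:
  dimensions:
  - 20.0
  - 7.0
  - 3.0
  h: 0.8
family: Q1NC
scheme:
  type: SI
  dt: 0.02
  t_end: 150.0
conductivity:
  d_l: 0.0952
  d_t: 0.0126
  fiber:
  - 1.0
  - 0.0
  - 0.0
stimuli:
- kind: volume
  region:
    type: box
    min:
    - 0.0
    - 0.0
    - 0.0
    max:
    - 1.5
    - 1.5
    - 1.5
  amplitude: 0.357142857142857
  start: 0.0
  duration: 2.0
probes:
- - 0.0
  - 0.0
  - 0.0
- - 20.0
  - 7.0
  - 3.0
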