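geometry:
  dimensions:
  - 50.0
  - 50.0
  - 1.0
  h: 1.0
family: Q1NC
scheme:
  type: SI
  dt: 0.005
  t_end: 600.0
conductivity:
  d_l: 0.0952
  d_t: 0.0952
  fiber:
  - 1.0
  - 0.0
  - 0.0
stimuli:
- kind: surface
  region:
    type: plane
    axis: 1.0
    value: 0.0
  amplitude: 0.12
  start: 0.0
  duration: 2.0
- kind: volume
  region:
    type: box
    min:
    - 0.0
    - 0.0
    - 0.0
    max:
    - 25.0
    - 25.0
    - 1.0
  amplitude: 0.15
  start: 280.0
  duration: 5.0
probes:
- - 25.0
  - 25.0
  - 0.0
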