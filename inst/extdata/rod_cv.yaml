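geometry:
  dimensions:
  - 25.0
  - 0.5
  - 0.5
  h: 0.5
family: Q1
scheme:
  type: SI
  dt: 0.001
  t_end: 250.0
conductivity:
  d_l: 0.0952
  d_t: 0.0952
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
    - 0.5
    - 0.5
    - 0.5
  amplitude: 0.2
  start: 0.0
  duration: 2.0
probes:
- - 18.0
  - 0.0
  - 0.0
- - 22.0
  - 0.0
  - 0.0
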