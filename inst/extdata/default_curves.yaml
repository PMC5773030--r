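f_lmax:
  - [0, 0.55]
  - [0.3, 0.9]
  - [0.5, 1]
  - [0.75, 0.8]
  - [1, 0.5]
f_l:
  - [0, 0]
  - [0.25, 0.1]
  - [0.5, 0.5]
  - [0.75, 0.9]
  - [1, 1]
f_lw:
  - [0, 0]
  - [0.3, 0.22]
  - [0.55, 0.28]
  - [0.8, 0.18]
  - [1, 0]
f_ang:
  - [0, 80]
  - [0.4, 65]
  - [0.7, 50]
  - [1, 35]
petiole_length_fraction: 0.5
petiole_width: 0.02
max_node: 20
maturation_plastochrons: 8
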