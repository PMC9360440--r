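# The three default 20-micron-class light sheets
beams:
  - type: gaussian
    na: 0.21
  - type: mb_square
    na_max: 0.35
    na_min: 0.25
  - type: hexagonal
    na_max: 0.46
    na_min: 0.36
    fill_factor: 1
grid:
  "n": 1025
n_medium: 1.33
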