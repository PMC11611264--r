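arena:
  length_mm: 55
  width_mm: 4
  borders_mm: [13.75, 27.5, 41.25]
  choice_halfwidth_mm: 3
  gradient_width_mm: 0.67
schedule:
  - {start_s: 0, end_s: 30, intensity_uW_mm2: 0, color: dark}
  - {start_s: 30, end_s: 90, intensity_uW_mm2: 1.3, color: red, lit_quadrants: [0, 2]}
  - {start_s: 90, end_s: 120, intensity_uW_mm2: 0, color: dark}
  - {start_s: 120, end_s: 180, intensity_uW_mm2: 5, color: red, lit_quadrants: [0, 2]}
  - {start_s: 180, end_s: 210, intensity_uW_mm2: 0, color: dark}
  - {start_s: 210, end_s: 270, intensity_uW_mm2: 22, color: red, lit_quadrants: [0, 2]}
  - {start_s: 270, end_s: 300, intensity_uW_mm2: 0, color: dark}
  - {start_s: 300, end_s: 360, intensity_uW_mm2: 70, color: red, lit_quadrants: [0, 2]}
group_label: test
metadata:
  driver: example-driver
  effector: CsChrimson
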