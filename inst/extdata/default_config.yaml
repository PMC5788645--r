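seed: 1
output_dir: fibrostage-out
cohort:
  stage_table:
    F0:
      'n': 16
      ADC:
      - 1.283
      - 0.138
      D_app:
      - 1.581
      - 0.192
      K_app:
      - 0.93
      - 0.083
      DDC:
      - 1.353
      - 0.268
      alpha:
      - 0.569
      - 0.073
    F1:
      'n': 16
      ADC:
      - 1.056
      - 0.151
      D_app:
      - 1.343
      - 0.183
      K_app:
      - 0.956
      - 0.08
      DDC:
      - 1.101
      - 0.173
      alpha:
      - 0.6
      - 0.071
    F2:
      'n': 16
      ADC:
      - 0.915
      - 0.131
      D_app:
      - 1.09
      - 0.171
      K_app:
      - 1.025
      - 0.093
      DDC:
      - 0.761
      - 0.147
      alpha:
      - 0.687
      - 0.075
    F3:
      'n': 17
      ADC:
      - 0.863
      - 0.109
      D_app:
      - 1.072
      - 0.16
      K_app:
      - 1.065
      - 0.085
      DDC:
      - 0.697
      - 0.129
      alpha:
      - 0.674
      - 0.067
    F4:
      'n': 15
      ADC:
      - 0.884
      - 0.088
      D_app:
      - 0.992
      - 0.095
      K_app:
      - 1.07
      - 0.083
      DDC:
      - 0.679
      - 0.146
      alpha:
      - 0.642
      - 0.066
  sigma: 0.02
  S0: 100.0
  generator_model: sem
  grid_size: 32
  pixel_size_mm: 0.78125
  jitter_sd: 0.0
  collagen_mean:
  - 2.0
  - 6.0
  - 12.0
  - 20.0
  - 30.0
  collagen_sd: 5.0
  b_values_mono:
  - 0.0
  - 800.0
  averages_mono:
  - 1
  - 3
  b_values_multib:
  - 0.0
  - 700.0
  - 1400.0
  - 2100.0
  averages_multib:
  - 1
  - 2
  - 3
  - 4
fitting:
  models:
  - mono
  - dki
  - sem
roi:
  n_rois: 5
  area_range_mm2:
  - 3.0
  - 4.0
statistics:
  roc_parameters:
  - ADC
  - D_app
  - DDC
  splits:
  - any_fibrosis
  - significant
  - advanced
  - cirrhosis
  replicates: 200
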