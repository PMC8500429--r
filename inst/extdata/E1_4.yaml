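# Sacroiliac-joint lesion task: inflamed vs normal bone marrow (in-house
# 28-patient dataset characterisation). Both IVIM and a deliberately
# simplified ADC model are fitted to IVIM-generated signals.
name: E1.4
task:
  positive_label: Inflamed
  negative_label: Normal
  classification_parameter: f
tissues:
  - label: Inflamed
    model: IVIM
    diffusivity_unit: 1e-3 mm^2/s
    means: {f: 0.07, d_slow: 1.91, d_fast: 24.2}
    sds:   {f: 0.08, d_slow: 0.56, d_fast: 28.5}
  - label: Normal
    model: IVIM
    diffusivity_unit: 1e-3 mm^2/s
    means: {f: 0.05, d_slow: 0.92, d_fast: 44.6}
    sds:   {f: 0.04, d_slow: 0.26, d_fast: 35.2}
design:
  b_values: [0, 50, 100, 300, 600]
  snr: 56.3
  n_per_tissue: 10000
  seed: 104
  fits:
    - {model: IVIM, method: bcNLLS, parameter: f}
    - {model: IVIM, method: bcNLLS, parameter: d_slow}
    - {model: IVIM, method: bcNLLS, parameter: d_fast}
    - {model: ADC, method: wLS, parameter: adc}
evaluation:
  orientation: auto
  subsample: {n_pos: 14, n_neg: 14, repeats: 1000}
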