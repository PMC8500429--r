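# Illustrative task: tissues differ only in tissue diffusivity d_slow
name: E2.2
task:
  positive_label: Active
  negative_label: Chronic
  classification_parameter: d_slow
tissues:
  - label: Chronic
    model: IVIM
    diffusivity_unit: 1e-3 mm^2/s
    means: {f: 0.12, d_slow: 0.46, d_fast: 123}
    sds:   {f: 0.0,  d_slow: 0.0,  d_fast: 0.0}
  - label: Active
    model: IVIM
    diffusivity_unit: 1e-3 mm^2/s
    means: {f: 0.12, d_slow: 0.60, d_fast: 123}
    sds:   {f: 0.0,  d_slow: 0.0,  d_fast: 0.0}
design:
  b_values: [0, 10, 20, 40, 80, 100, 200, 400, 600]
  snr: 20
  n_per_tissue: 10000
  seed: 202
  fits:
    - {model: IVIM, method: sNLLS, b_threshold: 50, parameter: d_slow}
    - {model: IVIM, method: bcNLLS, parameter: d_slow}
    - {model: ADC, method: wLS, parameter: adc}
evaluation:
  orientation: auto
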