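# Illustrative task: tissues differ only in perfusion fraction f
name: E2.1
task:
  positive_label: Chronic
  negative_label: Healthy
  classification_parameter: f
tissues:
  - label: Healthy
    model: IVIM
    diffusivity_unit: 1e-3 mm^2/s
    means: {f: 0.09, d_slow: 0.35, d_fast: 123}
    sds:   {f: 0.0,  d_slow: 0.0,  d_fast: 0.0}
  - label: Chronic
    model: IVIM
    diffusivity_unit: 1e-3 mm^2/s
    means: {f: 0.12, d_slow: 0.35, d_fast: 123}
    sds:   {f: 0.0,  d_slow: 0.0,  d_fast: 0.0}
design:
  b_values: [0, 10, 20, 40, 80, 100, 200, 400, 600]
  snr: 20
  n_per_tissue: 10000
  seed: 201
  fits:
    - {model: IVIM, method: sNLLS, b_threshold: 50, parameter: f}
    - {model: IVIM, method: bcNLLS, parameter: f}
    - {model: ADC, method: wLS, parameter: adc}
evaluation:
  orientation: auto
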