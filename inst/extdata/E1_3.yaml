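# Sacroiliac-joint lesion task: active lesions vs healthy bone marrow
# (external 41-patient dataset characterisation).
name: E1.3
task:
  positive_label: Active
  negative_label: Healthy
  classification_parameter: d_slow
tissues:
  - label: Active
    model: IVIM
    diffusivity_unit: 1e-3 mm^2/s
    means: {f: 0.12, d_slow: 0.99, d_fast: 123.9}
    sds:   {f: 0.03, d_slow: 0.39, d_fast: 19.9}
  - label: Healthy
    model: IVIM
    diffusivity_unit: 1e-3 mm^2/s
    means: {f: 0.09, d_slow: 0.34, d_fast: 122.7}
    sds:   {f: 0.02, d_slow: 0.09, d_fast: 18.3}
design:
  b_values: [0, 10, 20, 30, 50, 80, 100, 200, 400, 800]
  snr: 150.6
  n_per_tissue: 10000
  seed: 103
  fits:
    - {model: IVIM, method: sNLLS, b_threshold: 200, parameter: f}
    - {model: IVIM, method: sNLLS, b_threshold: 200, parameter: d_slow}
    - {model: IVIM, method: sNLLS, b_threshold: 200, parameter: d_fast}
evaluation:
  orientation: auto
  subsample: {n_pos: 14, n_neg: 13, repeats: 1000}
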