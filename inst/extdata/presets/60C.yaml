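label: 60C
model:
  hemoglobin_bands_oxy:
  - center: 417.0
    width: 15.0
    amplitude: 3.0
  - center: 545.0
    width: 10.0
    amplitude: 0.35
  - center: 575.0
    width: 10.0
    amplitude: 0.36
  hemoglobin_bands_deoxy:
  - center: 426.0
    width: 15.0
    amplitude: 3.2
  - center: 557.0
    width: 10.0
    amplitude: 0.55
  - center: 905.0
    width: 30.0
    amplitude: 0.1
  water_bands:
  - center: 1184.0
    width: 35.0
    amplitude: 0.35
  - center: 1441.0
    width: 45.0
    amplitude: 1.0
  oxygen_saturation: 0.03
  blood_amplitude_scale: 1.5
  water_amplitude_scale: 1.3
  scatter_a: 26.0
  scatter_b: 1.55
  lambda_ref: 500.0
  g0: 0.885
  g_slope: 2.0e-05
  baseline_mu_a: 0.1
  'n': 1.4
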