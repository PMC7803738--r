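label: 36C
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
  - center: 1192.0
    width: 35.0
    amplitude: 0.35
  - center: 1449.0
    width: 45.0
    amplitude: 1.0
  oxygen_saturation: 0.9
  blood_amplitude_scale: 1.0
  water_amplitude_scale: 1.0
  scatter_a: 18.5
  scatter_b: 1.25
  lambda_ref: 500.0
  g0: 0.918
  g_slope: 2.5e-05
  baseline_mu_a: 0.09
  'n': 1.4
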