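name: subthreshold_oscillations
parameters:
  tau_m: 0.3
  tau_h: 5.0
  tau_n: 1.5
  mu_m: -45.0
  mu_h: -62.0
  mu_n: -53.0
  s_m: 12.0
  s_h: -7.0
  s_n: 15.0
  gNa_max: 20.0
  gK_max: 36.0
protocol:
  dt: 0.1
  duration: 300.0
  I_amp: 10.0
  t_on: 50.0
  t_off: 250.0
expected_features:
  regime: subthreshold_oscillations
  min_spikes: 0
  max_spikes: 0
  osc_min_peaks: 2
  osc_min_amplitude_mV: 1
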