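name: transient_spiking
parameters:
  tau_m: 0.3
  tau_h: 25.0
  tau_n: 4.0
  mu_m: -40.0
  mu_h: -67.0
  mu_n: -53.0
  s_m: 9.0
  s_h: -7.0
  s_n: 15.0
  gNa_max: 120.0
  gK_max: 36.0
protocol:
  dt: 0.1
  duration: 300.0
  I_amp: 10.0
  t_on: 50.0
  t_off: 250.0
expected_features:
  regime: transient_spiking
  min_spikes: 1
  max_spikes: 4
  transient_window_ms: 50
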