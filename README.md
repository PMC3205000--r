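# hhtune — hands-on parameter exploration for a Hodgkin-Huxley neuron model

Fitting a conductance-based neuron model by hand usually means typing
numbers, rerunning, and losing track of what you tried. `hhtune` implements
the synthesizer workflow instead: model parameters are driven by control
events — `(element id, raw value)` tuples with 7-bit values 0–127, the
vocabulary of MIDI-class control surfaces — and the simulation reruns on
every event. Every session is recorded as a per-simulation parameter
trajectory and replays **deterministically**, so an interactive fitting
session doubles as a reproducible artifact and a regression test.

The package is aimed at computational neuroscientists and teachers who want
to *feel* how a model responds to its parameters: turn a knob, watch the
trace change, and keep the full history of the search.

## The model

A single membrane patch with sodium, potassium and leak currents:

$$C_m \dot V = -\bar g_{Na} m^3 h (V - E_{Na}) - \bar g_K n^4 (V - E_K)
  - g_L (V - E_L) + I(t)$$

re-parameterised for knob control: each gating variable
$x \in \{m, h, n\}$ has a sigmoidal steady state
$x_\infty(V) = 1/(1 + e^{-(V-\mu_x)/s_x})$ and a **voltage-independent**
time constant $\tau_x$,

$$\dot x = (x_\infty(V) - x)/\tau_x ,$$

so every gate is three orthogonal knobs — midpoint $\mu_x$ (mV), slope
$s_x$ (mV, sign = direction), time constant $\tau_x$ (ms). With the two
maximal conductances that is eleven kinetic parameters; adding the stimulus
amplitude, the default session binds twelve control elements. Gating
advances by explicit Euler, the voltage by an unconditionally stable
implicit-Euler update, so no knob position a user can reach makes the
integration blow up. The reference protocol is 300 ms at Δt = 0.1 ms with a
current step (density, µA/cm²) on [50, 250) ms.

## Worked example

Simulate the bundled tonic-firing preset, then run a short scripted
session that drags the model into a different firing regime:

```r
library(hhtune)

pre <- hh_preset("regular_spiking")
tr <- hh_simulate(pre$parameters, pre$protocol)
tr
#> <hh_trace> 3001 samples over 300 ms (dt = 0.1 ms); 14 spike(s); V in [-76.24, 45.31] mV
head(tr$spike_times, 5)
#> 51.7 67.3 82.4 97.5 112.6
classify_regime(tr)
#> "regular_spiking"

# three control events: element 7 = mu_h knob, element 4 = tau_h knob
ev <- data.frame(seq = 1:3, element_id = c(7, 4, 7), raw_value = c(50, 102, 42))
log <- run_session(session_config(backend = ev), quiet = TRUE)
log$records[, c("sim_index", "element_id", "raw_value", "parameter", "mapped_value")]
#>   sim_index element_id raw_value parameter mapped_value
#> 1         1          7        50      mu_h    -62.44094
#> 2         2          4       102     tau_h     25.67136
#> 3         3          7        42      mu_h    -66.85039
classify_regime(log$trace)
#> "transient_spiking"

tr2 <- replay_session(log, session_config())
identical(tr2$V, log$trace$V)
#> TRUE
```

Reading: the model starts as a tonic spiker (14 spikes spread over the
200 ms stimulus). Dropping the inactivation midpoint `mu_h` to −66.85 mV
and slowing its recovery (`tau_h` ≈ 25.7 ms) leaves sodium inactivation
accumulated during the step, so the cell fires only at stimulus onset —
the session log shows exactly which knob produced which value at which
simulation index, and the replay reproduces the final voltage trace
bit-for-bit.

`plot_trajectories(log)` draws the fitting history (raw value 0–127 per
touched parameter against simulation index);
`hh_presets()` lists the three bundled regimes (`regular_spiking`,
`subthreshold_oscillations`, `transient_spiking`), each with a scripted
fitting session under `inst/extdata/scripts/`.

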