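---
title: "Hands-on parameter tuning of a Hodgkin-Huxley model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hands-on parameter tuning of a Hodgkin-Huxley model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hhtune)
```

## The idea

Manual parameter fitting of neuron models is usually a keyboard-and-mouse
affair: edit a number, rerun, squint, repeat. `hhtune` implements the
alternative workflow of driving model parameters from a bank of physical or
virtual knobs: every control event (an element id plus a 7-bit value, the
message format of MIDI-class control surfaces) is mapped onto a model
parameter, the simulation is rerun immediately, and the whole interaction is
recorded so that any session can be replayed, audited and regression-tested
deterministically. The package bundles the model that this workflow is most
naturally demonstrated on — a Hodgkin-Huxley variant re-parameterised for
knob control — together with three frozen parameter sets exhibiting its
qualitative firing regimes.

## The model

A single isopotential membrane patch with sodium, potassium and leak
currents:

$$C_m \frac{dV}{dt} = -\bar g_{Na} m^3 h\,(V - E_{Na})
  - \bar g_K n^4\,(V - E_K) - g_L (V - E_L) + I(t)$$

Each gating variable $x \in \{m, h, n\}$ relaxes toward a voltage-dependent
steady state with a **voltage-independent** time constant:

$$\frac{dx}{dt} = \frac{x_\infty(V) - x}{\tau_x}, \qquad
  x_\infty(V) = \frac{1}{1 + \exp\!\big(-(V - \mu_x)/s_x\big)}$$

This differs from the textbook formulation (voltage-dependent rate functions
$\alpha_x(V)$, $\beta_x(V)$) in exactly the way an interactive tool wants:
each gate is described by three orthogonal, dimensionally meaningful numbers
— a midpoint $\mu_x$ (mV), a slope factor $s_x$ (mV, its sign giving the
direction: $s_m, s_n > 0$ activate with depolarisation, $s_h < 0$
inactivates) and a time constant $\tau_x$ (ms) — every one of which maps
cleanly onto a knob. With the two maximal conductances that is eleven
kinetic parameters; the stimulus amplitude makes twelve bound control
elements in the default session.

The remaining constants are fixed at classic squid-axon values and are
deliberately not knob-bound (they are overridable in configuration files):
$C_m = 1\,\mu F/cm^2$, $E_{Na} = 50$, $E_K = -77$, $E_L = -54.4$ mV,
$g_L = 0.3\,mS/cm^2$. The default kinetic values ($\tau_m = 0.3$,
$\tau_h = 5$, $\tau_n = 4$ ms; $\mu_m = -40$, $\mu_h = -62$, $\mu_n = -53$
mV; $s_m = 9$, $s_h = -7$, $s_n = 15$ mV; $\bar g_{Na} = 120$,
$\bar g_K = 36\,mS/cm^2$) are sigmoidal fits in the spirit of the original
steady-state curves and produce tonic spiking under the default protocol.

**Units of the injected current.** The model is a current-density model:
with $C_m$ in $\mu F/cm^2$ and conductances in $mS/cm^2$, the stimulus
`I_amp` is a density in $\mu A/cm^2$. For a dimensionless single
compartment only the ratio $I/C_m$ matters, so any absolute-current
convention differs only by a fixed area factor; we state the density
convention prominently rather than leaving it implicit.

**Protocol.** The reference protocol integrates 300 ms at
$\Delta t = 0.1$ ms with a current step on the half-open window
$[50, 250)$ ms. Half-openness avoids double-counting the boundary sample:
the current at step $i$ is the current over $[t_i, t_{i+1})$.

## Numerics

The integrator is semi-implicit, chosen for robustness under live parameter
dragging rather than raw accuracy:

1. **Gating: explicit Euler.** $x \leftarrow x + \Delta t\,
   (x_\infty(V_i) - x)/\tau_x$, evaluated at the *old* voltage. For
   $\Delta t \le \tau_x$ this is a convex combination and cannot leave
   $[0,1]$.
2. **Voltage: implicit (backward) Euler** with the freshly updated
   conductances held fixed:
   $$V_{i+1} = \frac{C_m V_i/\Delta t + g_{Na} E_{Na} + g_K E_K + g_L E_L + I}
     {C_m/\Delta t + g_{Na} + g_K + g_L}.$$
   The new voltage is a convex combination of $V_i$ and the
   conductance-weighted reversal potential (shifted by $I$), so the update
   is unconditionally stable — a user can push $\Delta t$ to 10 ms or a
   time constant to its floor without the trace exploding, which a fully
   explicit voltage update demonstrably does not survive (the package
   exposes `voltage_method = "explicit"` purely to make that comparison
   testable).

Supporting choices, each made once and frozen:

* **Gating at the old or new voltage?** The gating update reads
  $x_\infty$ at $V_i$, the natural reading of "conductances first, then the
  voltage from them"; at the step sizes involved the difference is second
  order.
* **Initial state.** $V_0$ defaults to the resting state of the full system
  at $I = 0$, found by damped fixed-point iteration on the
  conductance-weighted reversal potential (damping 0.2, tolerance
  $10^{-10}$ mV, fallback $E_L$ if 2000 iterations fail to converge, as can
  happen in bistable corners). Gating starts at $x_\infty(V_0)$. This
  avoids an onset transient that would otherwise pollute the first
  stimulus response.
* **Clamping, not crashing.** When a user drags $\tau_x$ below $\Delta t$
  mid-session the explicit gating step overshoots; values are clamped to
  $[0,1]$ and the number of clamp engagements is reported on the trace
  (`clamp_hits`). An interactive loop must never die under a legal knob
  position. Property tests assert the counter stays at zero whenever
  $\Delta t \le \min \tau_x$.
* **Non-finite guard.** A non-finite voltage aborts the run with the step
  index (error class `hhtune_nonfinite`); with the implicit update this is
  unreachable for valid inputs, but the guard protects the explicit mode
  and any future extension.
* **Lookup tables.** `sigmoid_lut()` tabulates $x_\infty$ on 2048 points
  over $[-100, 50]$ mV with linear interpolation (`stats::approxfun`,
  edge-clamped outside the range); the interpolation error is below
  $10^{-4}$ for slopes of a few mV, and `hh_simulate(use_lut = TRUE)` runs
  the whole integration through the tables — the classic speed optimisation
  for conductance-based models, kept optional because the exact path is the
  reference.
* **Spike detection** is an upward crossing of 0 mV
  ($V_{i-1} < \theta \le V_i$), reported at sample $i$, no refractory
  window. For full-height action potentials this is unambiguous, and it is
  all the regime classifier needs.

Accuracy is verified two ways rather than assumed: the passive membrane
($\bar g_{Na} = \bar g_K = 0$) is compared against the closed-form RC step
response (within 1% of the plateau excursion at $\Delta t = 0.05$ ms), and
the full model at $\Delta t = 0.001$ ms is compared against an independent
adaptive-step reference (a brute-force right-hand side handed to
`deSolve::lsoda` at tolerance $10^{-10}$, integrating each constant-current
segment separately): the subthreshold regime agrees to well under 0.5 mV
over a 100 ms window and spike times of the tonic regime to well under
1 ms. The fixed-step error also shrinks monotonically under step halving
($\Delta t = 0.1, 0.05, 0.025$ ms), as a first-order scheme should.

## The controller layer

Control surfaces speak in `(element id, raw value)` tuples with raw values
in 0–127. The layer above them has three pieces:

* **Layouts.** A `device_layout` declares the available elements. The
  bundled `uc33_layout()` emulates a common compact surface: 24 knobs and
  9 sliders (33 continuous elements, ids 0–32) plus 14 buttons (ids 33–46).
  The id assignment is this package's own convention; only the counts
  mirror the hardware.
* **Mappings.** A `parameter_binding` maps raw values onto `[low, high]`
  either linearly, $low + (r/127)(high - low)$, or exponentially,
  $low\,(high/low)^{r/127}$ (requiring $low > 0$; the right choice for
  scale-type parameters such as conductances and time constants, where one
  wants constant *relative* resolution). Both endpoints are assigned
  exactly rather than computed, so raw 0 and 127 hit the bounds with no
  floating-point slop; monotonicity and the exhaustive 128-value round trip
  through `unmap_raw()` are tested for both kinds.
* **Meta elements.** When a knob's range or precision turns out wrong
  mid-session, a second knob bound to the same binding rescales the
  interval on an exponential scale about its centre, relative to the
  *base* interval: the width scale is $1/4$ at raw 0, exactly 1 at the
  centre detent 64, and $4$ at raw 127 (piecewise exponents
  $4^{(r-64)/64}$ below the detent and $4^{(r-64)/63}$ above, the
  asymmetric denominators being the price of hitting both extremes exactly
  with 7-bit values — the same asymmetry MIDI pitch-bend lives with). After
  a meta event the primary parameter is re-derived from the primary
  element's last raw value under the new interval. The law is a package
  convention (any exponential rescaling would do) and is deliberately
  confined to one function, `apply_meta()`.

Backends deliver events. The **virtual backend** replays a CSV script
(`seq,element_id,raw_value`, validated at load: 7-bit range, strictly
increasing `seq`) and is the fully tested path; it also accepts recorded
session logs, closing the loop between live use and regression tests. A
**live MIDI backend** slot exists in the interface (`"midi:<port>"`,
control-change messages mapping 1:1 to events) but no R MIDI binding is
bundled, so it reports itself unavailable with a distinct error class;
nothing in the session layer knows the difference. Polling returns every
event accumulated since the last poll, in order — no coalescing by default,
because the per-event parameter trajectory is data we want to keep — with
an opt-in latest-value-per-element mode for models too slow to rerun per
event.

## The session loop and replay

`run_session()` is the closed loop: one baseline simulation before any
event (so a current trace always exists), then per applied event — primary
binding, meta binding, or bank-switching button press (raw 127 swaps the
active binding table; banks are declared in the config) — one parameter
update and one simulation rerun. The *simulation index* counts these
reruns and is the abscissa of the trajectory plot: it shows which
parameters the user worked on and in what order, independent of wall-clock
speed. Unbound elements are logged and skipped; nothing a controller can
emit aborts a session.

Every applied event becomes one `TrajectoryRecord` (simulation index,
element, raw value, parameter, mapped value, role, timestamp). Timestamps
are wall-clock and explicitly excluded from all replay comparisons — only
order is semantic. The log carries full initial and final parameter
snapshots plus a fingerprint of the binding tables; `replay_session()`
refuses a config whose bindings differ, then re-applies the raw events from
the initial snapshot. Because every stage is deterministic, the replayed
final trace is bit-identical to the live one — asserted over 100 seeded
random sessions (5 events each, every third including meta events) in the
test suite, and recomputed over 50 sessions by the acceptance script. Logs
serialise to JSON at full precision; a log that has been through disk
replays to the same bits, with a $10^{-12}$ relative tolerance on the
snapshot comparison absorbing the last-ulp wobble of decimal
serialisation.

## Presets: the three firing regimes

The three bundled parameter sets were found interactively with the
package's own tuning loop and then frozen, together with the declarative
criteria each must satisfy. The classifier (`classify_regime()`) is
deliberately simple and its thresholds are declared per preset and
overridable:

| preset | what changes vs default | mechanism |
|---|---|---|
| `regular_spiking` | nothing (defaults) | tonic firing: $\ge 5$ spikes spread across the stimulus window, the last in its final third |
| `subthreshold_oscillations` | $\bar g_{Na} = 20$, $\mu_m = -45$, $s_m = 12$, $\tau_n = 1.5$ | sodium too weak to reach threshold, but fast amplification against the potassium gate leaves a damped resonance: zero spikes and $\ge 2$ post-onset voltage maxima $\ge 1$ mV above the post-transient mean (measured over the second half of the window, after onset dynamics settle) |
| `transient_spiking` | $\mu_h = -67$, $\tau_h = 25$ | inactivation sits lower and recovers slowly: the step elicits spikes only within 50 ms of onset, then accumulated inactivation silences the cell |

All three sets were chosen with margin: they keep their classification at
$\Delta t = 0.05$ ms (the regimes are not integration artifacts) and under
the 128-step quantisation of the default bindings, so the bundled
"fitting session" scripts — short event scripts that drive the default
model into each regime, shipped under `inst/extdata/scripts/` — land in the
right class after raw-value round-tripping.

## What the synthetic sessions do and do not emulate

Scripted virtual sessions reproduce the *information content* of a live
session exactly: the event tuples, their order, and the deterministic
model response. They do not emulate a human in the loop — no reaction
latency, no overshooting a target and dialling back, no continuous
streams of intermediate values while a physical knob turns (a real surface
emits dozens of events per turn; scripts typically jump), and no hardware
timing jitter. Passing tests therefore certify the machinery — mapping,
bookkeeping, determinism, regime reproduction — not the ergonomics of
physical tuning, and latency (the property that makes or breaks the live
experience) is intentionally out of the tested surface.

## Problem sizes

The checks are sized to be decisive yet quick, and the same sizes are used
wherever the quantity is recomputed: 300 ms at $\Delta t = 0.1$ ms (3001
samples) for regime runs; 100 ms at $\Delta t = 0.001$ ms (100 001 steps)
for the oracle comparisons; 128-value exhaustive mapping round trips; 100
(tests) / 50 (acceptance script) randomized five-event replay sessions.
The full suite runs in well under a minute on one core.

## Known limitations

* Voltage-independent time constants are the point of the
  re-parameterisation, not an approximation bug — but they do mean the
  model cannot reproduce phenomena that hinge on $\tau_x(V)$ structure.
* One compartment, three currents, deterministic channels; no noise, no
  morphology, no other channel types.
* No automated optimisation — the package is the manual alternative, and
  the session log is the place where a human's search trajectory becomes
  analysable data.
* The classifier is a coarse qualitative instrument; parameter sets near
  regime boundaries can legitimately flip class under small perturbations,
  which is why the bundled presets were chosen away from the boundaries.
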