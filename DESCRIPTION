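Package: hhtune
Title: Hands-On Parameter Exploration for a Hodgkin-Huxley Neuron Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Closed-loop, hands-on parameter exploration for a modified
    Hodgkin-Huxley point-neuron model. A control-surface event layer (virtual
    scripted controllers with raw 0-127 values, linear or exponential
    parameter mappings, and range-reshaping meta-knobs) feeds live parameter
    updates into a continuously re-run simulation. The model uses sigmoidal
    steady-state activation curves with voltage-independent time constants,
    explicit-Euler gating updates and an unconditionally stable implicit-Euler
    voltage update. Sessions are recorded as per-simulation parameter
    trajectories and replay deterministically; three qualitative firing
    regimes (regular spiking, subthreshold oscillations, transient spiking)
    ship as presets with a regime classifier.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ggplot2,
    jsonlite,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
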