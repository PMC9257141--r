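Package: memneuro
Title: Simulation of Memristor-Capacitor and Resistor-Capacitor Neuron Circuits
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates first-order neuron-membrane circuit models in which the
    membrane leak is either a fixed resistor (RC) or a flux-controlled
    memristor (MC). Provides the piecewise memristance law with flux-state
    updates and pinched hysteresis loops, closed-form and forward-Euler
    charge/discharge transients with charge and power bookkeeping, a parallel
    membrane model driven by step, pulse-train, single-pulse and random
    stimuli with response classification, and a 2,000-neuron
    excitatory/inhibitory spiking network (Izhikevich-type) exhibiting
    asynchronous and synchronous regimes, with a population-rate synchrony
    index. Includes per-figure experiment presets, CSV/JSON serialization and
    a command-line entry point.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    tools,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
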