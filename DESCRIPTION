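Package: tcob
Title: Temporal Constrained Objects for Declarative Simulation of Neurons and Circuits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A time-stepped declarative simulation framework built on temporal
    constrained objects: classes whose attributes are time-indexed series
    variables governed by simple, conditional, and quantified constraints that
    a per-timestep solver maintains by local propagation, linear solving, and
    damped iteration. On top of the engine the package provides an AC-circuit
    component library (Ohm and Kirchhoff laws as constraints), Hodgkin-Huxley,
    Izhikevich, and adaptive exponential integrate-and-fire neuron models,
    conductance-based synapse kernels (single-exponential, alpha,
    double-exponential with AMPA/NMDA/GABA presets), and a small cerebellar
    granular-layer microcircuit (mossy fibre, granule, Golgi, Purkinje) wired
    through interface constraints, together with stimulus generators, CSV and
    spike-file input/output, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
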