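Package: ventilam
Title: Multi-Scale Simulation of Ventilation-Induced Airway Inflammation
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Desk-scale multi-scale simulator of mechanical-ventilation-induced
    airway inflammation. Couples a lumped-parameter Poiseuille model of a
    symmetric bifurcating airway tree driven by a ventilator inflow waveform,
    a quasi-static axisymmetric solver for a three-layer (epithelium,
    connective tissue, airway smooth muscle) Neo-Hookean/linear-elastic airway
    wall on an elastic foundation, and a stochastic cellular-automata model of
    the stretch-activated innate immune response (macrophages, fibroblasts,
    TNF/TGF reaction-diffusion fields, epithelial damage-heal-fibrosis
    transitions). Includes a fibrosis-driven tissue-stiffening feedback stage,
    reproducible seeded ensembles, fixture generators, and CSV/JSON/plot
    outputs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ggplot2,
    jsonlite,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
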