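Package: cflvisc
Title: Cell-Free Layer Viscosity Fields and Pressure Losses in Narrow-Gap
    Suspension Flows
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Heterogeneous viscosity modelling for particle-laden flows in
    narrow plane channels (gap heights around 150 micrometres) at Reynolds
    numbers 50-150, the regime of ventricular assist device gaps. Maps local
    particle volume fractions to local viscosity with the Einstein-Roscoe
    equation, describes cell-free layer development along the channel with a
    calibrated tilted-parabola law, assembles sectioned viscosity fields with
    step and local-distribution steady-state submodels under an exact
    height-average consistency constraint, and solves the variable-viscosity
    plane-Poiseuille problem to obtain wall shear stresses, pressure losses
    and normalized pressure-loss coefficients. Includes a synthetic generator
    for APTV-style wall-normal concentration profiles and the Student-t
    measurement-uncertainty formula used for pressure-loss experiments.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
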