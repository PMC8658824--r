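Package: thermoramp
Title: Enzyme Activation Thermodynamics from Temperature-Gradient Assays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates Arrhenius and transition-state activation parameters
    (Ea, dG, dH, TdS of the activation barrier) for enzymes from a single
    temperature-gradient steady-state experiment. Parses long-form
    spectrophotometer CSV files from temperature-controlled cuvette changers,
    converts absorbance to concentration by Beer-Lambert, estimates
    instantaneous velocities by rolling ordinary least squares, fits
    Michaelis-Menten parameters within temperature bins by Levenberg-Marquardt
    nonlinear least squares, and fits a weighted Arrhenius line whose slope and
    intercept yield the thermodynamic parameters via Eyring transition-state
    theory with full error propagation. Includes AICc model comparison of
    global versus per-dataset Arrhenius lines and a temperature-ramp assay
    simulator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
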