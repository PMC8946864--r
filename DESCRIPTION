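Package: implantheat
Title: Transient Heat Conduction in Dental Implants under Oral Thermal Loads
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Exact Fourier sine-series solution of the one-dimensional
    transient heat equation in a dental implant whose oral-cavity end is
    driven by an exponentially decaying thermal load (hot-beverage intake),
    with the bone end pinned at body temperature. Exposes the closed-form
    temperature field, the implant's intrinsic diffusion time, implant
    material presets, peak-temperature and exposure-time parameter studies,
    clinical threshold metrics (time above temperature, CEM43 thermal
    dose), and two independent numerical oracles (a Crank-Nicolson
    finite-difference solver and Runge-Kutta integration of the mode
    amplitude ODE) for verification. Includes a configuration-file driven
    command-line interface and deterministic CSV/JSON writers.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
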