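Package: supraspec
Title: Host-Guest Binding, Photophysics, and Electron-Density Topology for
    Supramolecular Dye Sensing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for fluorescent-dye / cucurbituril
    indicator-displacement studies. Fits 1:1 host-guest and competitive
    indicator-displacement binding isotherms by exact mass-balance
    equilibrium solvers with bootstrap uncertainties; determines relative
    fluorescence quantum yields by the reference-slope method and
    fluorescence lifetimes by iterative reconvolution against a measured
    instrument response function; convolutes electronic excitation tables
    into UV-vis spectra with Gaussian broadening and fits Beer-Lambert
    molar absorptivities; evaluates QTAIM local descriptors (electron
    density, energy densities, reduced density gradient) on
    Gaussian-primitive model wavefunctions, locates and classifies bond
    critical points, and builds NCI grids; and computes solvation-shell
    statistics (radial distribution functions, coordination numbers,
    geometric hydrogen-bond selection, nanodroplet extraction, occupancy
    maps) from trajectories. Seeded synthetic-data generators emulate
    every input so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
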