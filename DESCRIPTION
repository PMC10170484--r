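Package: isopress
Title: Surface Pressure-Area Isotherms of Surfactant Monolayers from
    Molecular Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes surface pressure-area isotherms of surfactant
    monolayers at the air-water interface from molecular-dynamics
    trajectories by two independent routes. The osmotic route converts
    the mean restoring force exerted on surfactants by semipermeable
    virtual walls (a flat-bottom planar restraint that lets solvent pass
    freely) into a two-dimensional surface pressure, and applies a
    semi-empirical correction based on the ratio of the interfacial
    thickness at infinite dilution to the thickness at the current
    molecular area. The classical route evaluates the Kirkwood-Irving
    surface tension from the diagonal anisotropy of the pressure tensor
    of a two-interface slab. The package reads extended-XYZ and a
    LAMMPS-dump text dialect, computes per-species density profiles and
    the 90-10 interfacial thickness, estimates uncertainties by block
    averaging, assembles compression or expansion isotherm sweeps, and
    ships a self-contained Langevin-dynamics simulator of a minimal
    solvent-slab plus monolayer system used for testing and validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
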