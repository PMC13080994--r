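Package: cspkit
Title: Differentiable Rigid-Body Molecular Crystal Modelling and Structure Search
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "maintainer@example.org")
Description: Tools for modelling homomolecular (Z' = 1) organic molecular
    crystals as rigid bodies in a reduced 12-parameter representation: cell
    lengths and angles, fractional centroid in the asymmetric unit, and an
    axis-angle orientation. Provides canonical molecule standardization via
    principal inertial axes, a built-in table of the dominant organic space
    groups with general-position operators and asymmetric-unit bounds, crystal
    construction by symmetry, periodic cluster carving, Lennard-Jones,
    softened-repulsion and short-range electrostatic intermolecular energies
    with analytic gradients with respect to the crystal parameters,
    atom-type-pair radial distribution functions with an earth mover's
    distance similarity metric, and a two-stage gradient-based crystal
    structure search from random seeds at a target packing coefficient.
    Includes XYZ and minimal CIF input/output and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
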