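Package: bonevpd
Title: Orthotropic Visco-Plasto-Damage Modelling of Bone Tissue at the
    Material Point
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Material-point simulation of an orthotropic visco-plasto-damage
    constitutive model for cortical and trabecular bone: orthotropic
    elasticity degraded by a scalar damage variable, a Tsai-Wu-type yield
    surface with isotropic hardening/softening and kinematic hardening, and
    Perzyna-type viscoplastic flow, integrated by an elastic-predictor /
    plastic-corrector return mapping solved with Newton-Raphson. Includes
    strain-controlled, mixed-control uniaxial and ramp-and-hold relaxation
    test drivers, a power-law relaxation calibration procedure that reduces
    the yield-strain parameters to their long-time equilibrium values, an
    octree nearest-neighbour index for assigning local orthotropic material
    axes from point clouds, and deterministic synthetic-fixture generators
    for all inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
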