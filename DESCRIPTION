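Package: pedsim
Title: Forward-Dynamics Simulation of Foot Mechanics During Stance
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Anatomically structured, reduced-order forward-dynamics model of
    the human foot for simulating foot-ground interaction. Provides a
    procedurally generated 23-bone rigid skeleton, Ogden hyperelastic and
    Prony-series viscoelastic plantar soft tissue, tension-only ligament
    chains with slack lengths, a ten-slip plantar aponeurosis with
    metatarsal-head cylinder wrapping, penalty-based frictional ground
    contact, explicit symplectic time integration, three loading protocols
    (cadaveric-style axial loading, quiet standing, and marker-driven
    stance), a polynomial ground-reaction-force tracking refinement of the
    tibial trajectory, and y-x-z Euler joint kinematics with plantar
    pressure and center-of-pressure post-processing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    signal
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
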