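Package: brainunit3d
Title: Deterministic 3D Brain Unit Model of Local Drug Distribution in Brain Tissue
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates local pharmacokinetics of a drug inside a cubic unit of
    brain tissue whose ribs are occupied by blood capillaries. Couples a
    Bateman oral-absorption plasma forcing and upwind capillary advection to a
    reaction-advection-diffusion system for the brain extracellular fluid
    (ECF), with passive and saturable (Michaelis-Menten) transport across the
    blood-brain barrier (BBB) and reversible specific and non-specific
    binding. Provides a geometry-aligned finite-volume discretization, stiff
    method-of-lines integration, mass audits, parameter-sweep experiment
    drivers, and a Renkin-Crone capillary-extraction validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    Matrix,
    yaml,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
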