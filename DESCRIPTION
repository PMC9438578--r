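Package: aortaflow
Title: Arterial Strain-Energy and Fluid-Structure Models of Blood Supply
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Closed-form calculators for the strain energy stored in the
    deformed aortic wall between diastole and systole and for the mean blood
    supply it can sustain, built on thin-walled (Laplace) vessel mechanics and
    a Hamilton-principle fluid-structure coupling of wall and blood. Computes
    the strain energy density increment from clinically measurable parameters
    (systolic/diastolic pressure, aortic diameter and wall thickness,
    circumferential elastic modulus, expansion constraint coefficient),
    derives a characteristic per-pulse velocity with a laminar coupling
    dissipation coefficient, and converts it to per-pulse and per-minute
    flow. Includes an inverse solver for diastolic pressure under an
    equal-flow matching rule, processing of pressure-diameter expansion-test
    and circumferential stress-strain curves (exponential and linear-window
    fits, strain-energy integration), seeded synthetic-data generators,
    sensitivity sweeps, worked clinical examples, and a small command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
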