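Package: follisim
Title: Beam-and-Spring Simulation of Whisker Deformation in the Follicle
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quasi-static finite-element model of a whisker (vibrissa) and
    its follicle sinus complex: the whisker as an Euler-Bernoulli beam, the
    follicle wall as a rigid beam, and the surrounding tissue as six linear
    springs. Solves the 20-degree-of-freedom system under a prescribed
    deflection angle by the penalty method, reconstructs absolute, wall and
    relative displacement profiles along the follicle, classifies profiles
    into C-, S1- and S2-shapes by their zero crossings, tests them against
    ex vivo displacement constraints, and runs stiffness parameter sweeps
    for hair-bulb sensitivity, internal-spring feasibility, external
    (muscle) support and ring-sinus blood pressure.
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
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
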