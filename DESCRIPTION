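Package: ecathsim
Title: Electrochemical Hypochlorous Acid Generation and Transport in Catheters
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates in situ electrochemical generation of hypochlorous
    acid (HOCl) from saline inside an electrified intravascular catheter.
    Couples Butler-Volmer electrode kinetics with Nernst concentration
    feedback, kinetically-relaxed acid-base equilibria, a four-reaction
    HOCl degradation network, and one-dimensional variable-cross-section
    diffusive transport along the hub/Luer/tube geometry, integrated with
    a stiff method-of-lines scheme. Provides scenario presets for
    hub-only electrodes, elevated working-electrode potentials, extended
    working electrodes, and surface-area-matched designs, plus
    conservation audits and independent analytic/brute-force oracles.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    pracma,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
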