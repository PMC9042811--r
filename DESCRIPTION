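Package: znspec
Title: Equilibrium Speciation of Zinc with Citrate and Desferrioxamine B
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Chemical equilibrium speciation of Zn(II) in the presence of the
    weak tricarboxylate ligand citrate and the trihydroxamate siderophore
    desferrioxamine B (DFOB) in NaCl media. Ships the ionic-strength dependent
    stability-constant scheme for the Zn/citrate/DFOB system (conditional
    constants at 0.05-1.0 mol/dm3 and intrinsic constants with an extended
    Debye-Hueckel parametrisation), a damped-Newton mass-balance speciation
    solver, Davies and extended Debye-Hueckel activity corrections with
    Monte-Carlo confidence intervals, ligand-exchange-point and
    dominance-window analysis along pH and ionic-strength gradients, and a
    forward/inverse potentiometric-titration toolkit (electrode calibration,
    curve simulation, joint refinement of formation constants).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
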