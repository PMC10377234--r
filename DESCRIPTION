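Package: gjqsar
Title: QSAR, Docking Calibration, Grid-Field 3D-QSAR and Dose-Response
    Analysis for Gap-Junction Inhibitors
Version: 1.0.0
Authors@R:
    person("gjqsar", "developers", email = "gjqsar@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for the in-silico and electrophysiological
    evaluation of connexin-43 (Cx43) gap-junction inhibitors.  Provides the
    curated 17-compound inhibitor dataset with measured potencies and
    molecular descriptors; exhaustive best-subset multiple linear regression
    for descriptor-based QSAR with the packaged three-descriptor Cx43 model;
    an affine calibration mapping docking minimized affinity (kcal/mol) to
    potency on the -log10 molar scale; a grid-based 3D-QSAR engine computing
    steric (Lennard-Jones) and electrostatic molecular interaction fields on
    a regular lattice and regressing them on activity by partial least
    squares; junctional-conductance computation from dual patch-clamp
    voltage-ramp measurements and three-parameter Hill dose-response
    fitting; and seeded synthetic-data generators so every stage can be
    validated by parameter recovery without external inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
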