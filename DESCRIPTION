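Package: blastrat
Title: Desk-Scale Simulation of Blast Lung Injury in a Synthetic Rat Model
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation chain for primary blast lung injury at desk scale: an
    empirical scaled-distance charge/overpressure model with a linear-ramp
    source waveform, a synthetic layered tetrahedral rat body (skin/muscle,
    rib cage, heart, paired lungs) with named lung monitor points, a
    simplified analytic blast propagation model (incident overpressure,
    reflection coefficient, ground-image superposition) loading the body
    surface, a linear-elastic tetrahedral finite element solver producing
    von Mises stress on the lung surface, and the validation statistics
    (Pearson correlation per standoff and side, paired t-tests against an
    untreated group) that pair simulated lung-surface pressures with Smith
    pathology scores. Includes a synthetic pathology-score generator with a
    pressure-linked noise model for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
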