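Package: lncoord
Title: Lanthanide-Peptide Coordination Dynamics and Binding Thermodynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for the coordination chemistry of lanthanide
    ions (La through Lu) bound by short EF-hand-derived peptides such as the
    lanthanide binding tag. Provides hysteresis-threshold calling of
    coordination and dissociation events on donor-ion distance series,
    monodentate/bidentate chelation-mode classification for carboxylate
    ligands, first-shell water counting and five-state complex
    classification with transition bookkeeping, radial distribution
    functions with running coordination numbers, distance-resolved free
    energy profiles with basin-depth differences, a one-site isothermal
    titration calorimetry forward model and fitter with a
    fixed-stoichiometry fallback, and lanthanide-series thermodynamic
    decomposition (delta-delta quantities, branch-point detection, regime
    classification). A synthetic-data module generates labelled
    coordinate trajectories and ITC thermograms with known ground truth so
    every stage is testable without molecular dynamics output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    optparse,
    bio3d,
    withr
Config/testthat/edition: 3
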