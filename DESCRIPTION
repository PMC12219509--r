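Package: sterictrap
Title: Steric-Trapping Binding Models and Membrane-Protein Folding Energetics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative machinery for membrane-protein folding thermodynamics:
    steric-trapping binding models that convert monovalent-streptavidin (mSA)
    binding isotherms into folding free energies, cooperativity (delta-delta-delta-G)
    profiling with burial-stratified regression and Chow's test, bicelle
    physical-property estimators (effective lipid-to-detergent ratio, ideal-mixing
    critical bicelle concentration, Laurdan generalized polarization, gel-fluid
    transition temperature, SAXS-peak bilayer thickness), residence-time and
    solvation-free-energy analysis of amphiphile-protein contacts from molecular
    dynamics derived contact tables, and a three-state chemical-denaturation
    folding model. Every fitting and classification stage is backed by seedable
    synthetic-data generators with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
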