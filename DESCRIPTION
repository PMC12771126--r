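Package: confunnel
Title: Conformer-Ensemble Funnel Analysis for Flexible Drug-Like Molecules
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing pipeline for quantum-chemistry conformer
    ensembles of flexible drug-like molecules such as fentanyl and its
    analogs. Reads multi-structure XYZ ensembles with per-conformer
    electronic energies and harmonic frequencies, removes duplicate
    conformers by the rotational-constant/energy rule, extrapolates
    electronic energies to the complete-basis-set limit with the
    three-point 4-5 inverse-polynomial scheme, computes rigid-rotor
    harmonic-oscillator thermodynamic corrections with scaled frequencies
    at physiological temperature, derives Boltzmann populations and
    ensemble stabilization free energies, classifies phenyl-ring
    cis/trans/gauche conformations, and computes atom-matched RMSDs via
    Kabsch superposition with Hungarian atom assignment. A synthetic
    ensemble generator with planted ground truth supports end-to-end
    validation without electronic-structure calculations.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
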