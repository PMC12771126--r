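---
title: "Methods: conformer-funnel analysis with confunnel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conformer-funnel analysis with confunnel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(confunnel)
```

## The problem

Flexible, drug-like cations such as protonated fentanyl analogs occupy many
thermally accessible conformations in water at physiological temperature.
Ensemble properties — which conformer dominates, how much the ensemble as a
whole is stabilized relative to its best single structure, which phenyl-ring
arrangement prevails — require post-processing thousands of
electronic-structure results consistently. `confunnel` implements that
post-processing: it consumes conformer geometries, electronic energies at
labelled basis-set levels, and harmonic frequencies, and produces relative
free energies, Boltzmann populations, stabilization corrections,
conformation censuses and RMSD comparisons. It never runs quantum chemistry
itself; the synthetic generator stands in for those codes during testing.

## The funnel model

`run_pipeline()` executes the stages in a fixed order per analog:

1. **Duplicate removal.** Conformer samplers emit near-identical structures.
   Two conformers are duplicates when all three rotational constants agree
   within `rot_tol` (relative, default 0.01) *and* their energies agree
   within `e_tol` (default 0.1 kcal/mol). Conformers are sorted by energy
   (ties by id) and scanned greedily against the kept set, which makes the
   outcome independent of file order and keeps the lowest-energy member of
   each duplicate group. The tolerance relation is not transitive; for
   chains that straddle the tolerances the greedy result can differ from a
   connected-component analysis. The test suite checks both regimes: exact
   agreement with the component oracle for well-separated clusters, and
   locally consistent (never silent) decisions on adversarial chains. The
   relative difference uses the kept, lower-energy conformer as the
   denominator; requiring all of A, B, C is the strict reading of
   "rotational constants within 1%", and an any-constant variant is exposed
   via `all_constants = FALSE`.

2. **Electronic-energy window.** Expensive coupled-cluster refinement is
   limited to conformers whose *electronic* energies (the `DFT` level by
   default, matching how such funnels are run in practice) lie within
   `window` (default 8 kcal/mol) of the analog minimum. The boundary is
   inclusive; the choice is ours to make since "within" does not specify
   the edge, and inclusivity is the conservative option.

3. **Thermochemistry.** Plain ideal-gas RRHO at `temperature` (default
   310.15 K, human physiological) and `pressure` (1 bar): Sackur–Tetrode
   translation, classical rotation from the principal moments of inertia
   with symmetry number 1 (conformers of these molecules are asymmetric),
   and quantum harmonic vibrations over frequencies scaled by
   `scale_factor` (default 0.971, the accepted factor for
   ωB97X-D/6-31++G** harmonics). Scaling is applied uniformly, including
   the zero-point term — the natural reading of a single multiplicative
   anharmonicity correction. No quasi-RRHO damping of low modes is applied:
   the protocol this package supports treats scaled harmonics as the
   anharmonicity correction, and mixing two corrections would
   double-count. Electronic degeneracy is 1 (closed-shell ligands).
   `standard_state_offset()` reports the 1 bar → 1 mol/L correction
   (≈ 2 kcal/mol at 310 K) but the pipeline never adds it: it is constant
   across conformers of one molecule and cancels in relative energies.

4. **Composite free energies.** G = E(level) + G°corr, with E in hartree
   and G°corr converted at 627.509474 kcal/mol per hartree. The default
   level is `CBS(DTQ)`, built on the fly from the DZ/TZ/QZ ladder by the
   three-point extrapolation

   E_CBS = (243·E_DZ − 2048·E_TZ + 3125·E_QZ) / 1320.

   Mapping the zeta levels D, T, Q to N = 3, 4, 5 makes these coefficients
   (3⁵, 2·4⁵, 5⁵) annihilate both terms of an E_N = E∞ + aN⁻⁴ + bN⁻⁵
   convergence form exactly; that is the only index convention under which
   the printed coefficients form an exact 4–5 scheme, and the package
   treats it as definitional. The scheme is linear, so extrapolating
   absolute energies and then subtracting the minimum is identical to
   extrapolating relative columns (a property the tests assert), which is
   why published relative-energy tables can be fed directly to
   `basis_convergence_report()`.

5. **Populations and stabilization.** Boltzmann percentages and the
   ensemble stabilization ΔG°{A} use R = 1.987204259×10⁻³ kcal mol⁻¹ K⁻¹.
   `boltzmann_percentages()` refuses an ensemble not asserted complete:
   populations computed over a partial high-population subset (say, only
   the conformers refined with heavy-augmented basis sets) have an
   incomplete denominator and are systematically wrong. Population cutoffs
   ("above 0.5%", "above 5%") use strict inequality.

6. **Classification and census.** Conformations are labelled by the angle
   between the two vectors from the anchor nitrogen to the aromatic-ring
   centroids: cis below `cis_max` (60°), trans at or above `trans_min`
   (135°), gauche between. The qualitative taxonomy ("approximately
   parallel", "~90°", "~180°") fixes only the exemplars, not the
   boundaries; 60° and 135° are generous midpoints and are exposed as
   configuration. The anchor-to-centroid metric is used rather than
   ring-plane normals because it tracks ring *position* and is robust to
   ring tilt; a plane-normal metric is available via `metric = "normal"`.
   Aromatic rings are planar all-carbon six-cycles (mean out-of-plane
   deviation ≤ 0.1 Å) on a bond graph perceived from covalent radii with a
   0.45 Å additive tolerance. Heteroaromatic R-group variants (furan,
   thiophene) are classified by supplying their ring atom sets explicitly.

## Atom-matched RMSD

`rmsd_aligned()` superposes with the Kabsch algorithm (proper rotations
only). With `match_atoms = TRUE`, atom correspondence within each element
class is chosen by minimum-cost assignment (an O(n³) Hungarian solver) and
the assign ↔ superpose cycle is iterated until the mapping is stable
(capped at 50 iterations). Because the joint rotation-plus-assignment
problem is non-convex, the iteration is restarted from a deterministic set
of orientations — identity, a sorted-distance-from-centroid seeding, and
the 24 octahedral rotations applied after principal-axis alignment — and
the best result kept. The test suite validates the matched RMSD against
exhaustive enumeration of all within-element permutations on structures of
up to 8 atoms. RMSDs are all-atom and mass-unweighted by default, with a
`heavy_only` flag.

## The synthetic generator

`generate_ensemble()` emulates the *statistical* structure of a real analog
ensemble so every downstream stage has a planted ground truth:

* **Geometry.** Each conformer is a two-ring probe: a chair-form saturated
  six-ring containing the anchor nitrogen, and two planar six-carbon rings
  placed so the anchor-to-centroid separation equals a class-controlled
  angle (cis drawn from 5–50°, gauche 65–130°, trans 140–178°), with 0.02 Å
  coordinate jitter and a random rigid reorientation. Idealized bond
  lengths (aromatic C–C 1.39 Å, ring C–C 1.53 Å) suffice because
  classification depends only on ring placement.
* **Class mixture.** Defaults cis 0.57 / trans 0.12 / gauche 0.31, the
  approximate split observed across fentanyl-family ensembles;
  apportionment is largest-remainder, so planted counts are exact.
* **Energies.** A planted free-energy ladder: the reference at 0 and the
  rest uniform on [0, `dg_spread_kcal`] (default 8 kcal/mol, matching the
  funnel window; published per-analog spreads below the window are not
  available, so a uniform spread is an assumption, documented as such).
  The planted CBS limit of each conformer is back-computed so that the
  composite free energy (CBS electronic + that conformer's own RRHO
  correction) reproduces the planted ladder exactly; DZ/TZ/QZ energies are
  the planted limit plus a·N⁻⁴ + b·N⁻⁵ (defaults a = 15, b = −10 hartree,
  giving a realistic ≈ 0.14 hartree double-zeta error), optionally with
  declared Gaussian noise. The DFT level is the CBS limit plus a constant
  0.5 hartree, so relative DFT energies differ from relative free energies
  only by thermal-correction variation, as in real data.
* **Frequencies.** One base set of 3N−6 positive modes per analog (twelve
  low modes at 30–300 cm⁻¹, the rest at 400–3200 cm⁻¹), perturbed by 2%
  per conformer. Sharing a base set keeps the conformer-to-conformer
  spread of G°corr at realistic tenths of a kcal/mol — conformers of one
  molecule share bonding — rather than the tens of kcal/mol that fully
  independent draws would produce.
* **Determinism.** A single integer seed drives every draw through an
  isolated RNG scope; the global random state is saved and restored, and
  two calls with the same spec are bit-identical.

What the generator does *not* emulate: real potential-energy surfaces,
solvation physics, anharmonic couplings, or correlated geometry/energy
relationships. Passing the parameter-recovery tests therefore demonstrates
the correctness of the bookkeeping, the formulas and their composition —
not the accuracy of RRHO or CBS extrapolation on real molecules.

## Numerical choices

* Physical constants are CODATA 2018, collected in `physical_constants()`;
  masses are most-abundant-isotope values; hartree → kcal/mol is
  627.509474.
* Energies are carried in hartree internally and converted to kcal/mol
  only at reporting boundaries.
* Relative-energy references break ties by lexicographically smallest
  conformer id, making reports reproducible under reordering.
* Linear geometries are detected by a vanishing smallest principal moment
  (relative threshold 10⁻¹⁰) and handled with the 3N−5 mode count and the
  linear-rotor partition function; a single atom has translational terms
  only.
* `relative_gibbs()` refuses mixed level labels, which prevents the easy
  mistake of referencing heavy-augmented energies against a plain-basis
  minimum.

## Problem sizes in the test suite

The suite validates against closed forms and brute force at sizes where
the oracles are exact and fast: ≤ 8-atom structures for exhaustive RMSD
permutation search (50 cases), ≤ 20-conformer ensembles for the
deduplication component oracle (100 cases), 1000 random triples for
extrapolation exactness, 100 random ensembles for the Boltzmann
identities, and five 45-conformer synthetic ensembles (225 conformers) for
classifier census recovery. These sizes exercise every code path while
keeping the default test run fast.

## Known limitations

* Aromaticity perception is limited to planar all-carbon six-rings —
  sufficient for phenyl, but heteroaromatic rings must be supplied
  explicitly to the classifier.
* The dedup rule is rotational-constant based, as sampling workflows use;
  no RMSD-based deduplication is attempted at that stage.
* Published funnel summaries bundled with the package
  (`analog_funnel_summary()`, `analog31_zeta_energies()`,
  `fentanyl_pharmacology()`) are reference inputs; regenerating them
  requires the underlying quantum-chemistry data set, which is out of
  scope here.
* Whether published RMSD comparisons for this family are all-atom or
  heavy-atom is not documented; the default is all-atom with a
  `heavy_only` flag.
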