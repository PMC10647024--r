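---
title: "Strain energy of bound conformations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Strain energy of bound conformations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(confstrain)
```

## The problem and the model

A ligand bound to a protein or nucleic acid usually adopts a conformation
above its global energy minimum; binding pays the strain. For each ligand
the package compares the optimized energy of the bound pose, `E_active`,
with the energies of an optimized conformer ensemble. With `E_min` and
`E_max` the ensemble extremes and `E_global = E_min` the global
conformation (the bound pose is *not* a candidate — the global
conformation is by definition the best member of the generated ensemble),
three scenarios are possible:

1. `E_active < E_min` — the generator never found a conformer as good as
   the bound pose (scenario `below_min`);
2. `E_min ≤ E_active ≤ E_max`, boundaries inclusive (`within`);
3. `E_active > E_max` (`above_max`).

The strain energy is `ΔE = E_active − E_global`. The analysis cohort
("subset 2") is `within`-scenario ligands with `0 ≤ ΔE ≤ 20` kcal/mol,
the cutoff inclusive; ligands with negative ΔE form subset 1 and ligands
beyond the window subset 3. Subset membership and scenario agree by
construction on the subset-1/below-min boundary, and the package tests
this invariant.

All energies are kcal/mol and all coordinates Angstrom throughout;
atomic units appear at exactly one boundary (the optimizer's convergence
test, below), with 1 Hartree = 627.509474 kcal/mol and 1 Bohr =
0.529177210903 Å as documented constants.

## The CG-BS optimizer

`cgbs_optimize()` is a Cartesian conjugate-gradient minimizer with a
backtracking line search, built for potential-energy surfaces that are
locally rough (committee ML potentials), where quasi-Newton model trust
is easily misplaced.

* **Direction.** Polak–Ribière+ update,
  `β = max(0, gᵀ(g − g_prev)/‖g_prev‖²)`, restarting to steepest descent
  whenever the direction is not a descent direction, on a schedule (every
  `restart_interval` steps, default one per degree of freedom), or after
  a Wolfe-curvature violation (below). PR+ with restarts is the standard
  robust choice when curvature information is unreliable.
* **Line search.** Backtracking from a trial step with shrink factor 0.5
  until the Armijo sufficient-decrease condition holds
  (`c1 = 10⁻⁴`). The Wolfe curvature condition (`c2 = 0.9`) is then
  *checked* on the accepted step; if violated the step is still accepted
  (it decreased the energy) but a steepest-descent restart is scheduled,
  since the conjugacy assumption is broken. The trial step starts at 1.0
  and is warm-started at twice the previously accepted step, capped at
  4.0, which keeps the number of backtracking evaluations small.
* **Convergence quartet.** After each accepted step the gradient and the
  step are converted to atomic units and tested against the four
  thresholds 4.5·10⁻⁴ / 3.0·10⁻⁴ Hartree/Bohr (max / RMS force) and
  1.8·10⁻³ / 1.2·10⁻³ Bohr (max / RMS displacement). "Max" is the largest
  per-component magnitude and RMS runs over all 3N components; all four
  comparisons are inclusive, and optimization stops only when all four
  hold simultaneously. The iteration cap defaults to 10,000 so that
  difficult surfaces still terminate converged.
* **Failure mode.** If no decreasing step above 10⁻¹² exists (a cusp or a
  numerically flat region), the optimizer returns normally with
  `termination_reason = "line_search_failure"` rather than raising — a
  cohort run must never abort on one ligand.
* **Determinism.** The optimizer contains no randomness: identical inputs
  give bit-identical traces.

Accepted steps satisfy Armijo, so the traced energy sequence is
non-increasing — a property the test suite asserts on every trace it
produces. For oracle comparisons on analytic surfaces (Rosenbrock,
Lennard-Jones) the tests tighten the quartet to 10⁻⁸ au: the Gaussian
defaults are calibrated for molecular forces in kcal/mol/Å, and on the
shallow Rosenbrock valley they fire long before the interesting minimum
is reached. That is a parameter choice, not a tolerance change: the
comparison against `stats::optim` is still at 10⁻⁴ kcal/mol.

## Potentials

All potentials share one evaluation contract (energy, analytic gradient,
optional per-member energies). The analytic surfaces (harmonic well,
Lennard-Jones, 2D Rosenbrock) have closed-form minima and exist to prove
the optimizer. The *mock committee* potential emulates the structure of
an ensemble-of-models ML potential without any trained weights: a smooth
soft-minimum over k harmonic wells,

`E_base(x) = −τ · log Σ_j exp(−(½k‖x − c_j‖² + d_j)/τ)`,

with per-member constant offsets; the committee energy is the member
mean. τ defaults to 1 kcal/mol — small enough that wells several Å apart
are effectively independent, large enough that the surface stays smooth.
Real force fields and ML committees enter through adapter contracts
(user-supplied calculator closures; a convenience calculator shells out
to Open Babel's `obenergy`). The committee reliability statistic is
`ρ = sd(member energies)/√N_atoms`; whether the sd is sample or
population is not fixed by convention, so it is a documented switch
(`sample = TRUE` by default, the n−1 denominator).

## Molecule identity and RMSD

Conformer generators may renumber atoms, rename them, or "fix" a
molecule (add hydrogens, change protonation). Identity is therefore
verified structurally: for every atom, the multiset of element-labelled
simple paths (no repeated atom) of up to `depth` atoms is computed;
two molecules match only if a bijection exists that respects these
per-atom signatures *and* maps the bond set exactly. Design choices:

* **Depth 8 by default.** The depth is not dictated by the method; 8
  bonds separates all constitutional isomer pairs in the fixture library
  while keeping enumeration cheap on 20–60-atom molecules. Pathological
  symmetry at a given depth is detected by a node budget on the mapping
  search and surfaces as an explicit ambiguity error inviting a larger
  depth — never as a wrong answer.
* **Per-atom signatures, not pooled.** Pooling all paths per molecule is
  weaker (two non-isomorphic graphs can share a pooled multiset);
  per-atom signatures are stricter and prune the search sharply.
* **Hydrogens count.** A generator that adds an H produces a different
  molecule; that detection is the point.
* **Bond orders are ignored** — paths are element-based only, which is
  robust against generators that perceive bond orders differently.
* **Determinism.** Signature classes are searched smallest-first with
  index-order tie-breaks.

`kabsch_rmsd()` superposes by SVD with the determinant correction, so
only proper rotations are allowed: enantiomeric geometries keep a
non-zero RMSD, consistent with treating chirality as molecule identity.
The test suite checks it against an independent quaternion
(Horn-method) oracle at 10⁻¹⁰.

## Conformer generation

The default generator drives torsions: random (seeded) or grid-enumerated
rotations about every rotatable bond. A bond is rotatable when it is
acyclic, both ends have degree ≥ 2, and rotation moves at least one heavy
atom (methyl-type rotations produce no distinguishable conformers).
Rotating a rigid subtree about a bond axis cannot change connectivity or
chirality — and chirality is nevertheless *verified* on every output
against the seed's signed-volume signature at four-coordinate centres.
Clashing geometries (non-bonded contact < 0.7 Å) and exact duplicates are
discarded. Sampled ensembles aim at `min(max_conformers, 3^n_rotatable)`
members, mirroring how torsion count drives real ensemble sizes; the cap
defaults to 200. Externally generated ensembles (multi-mol2/SDF) can be
ingested instead, in which case the identity filter does the vetting.

A distance-geometry embedder was considered for the generator contract
and rejected: seeded torsion driving achieves the contract's guarantees
(determinism, stereo preservation, no external licenses) with far less
numerical machinery, and external ensembles can always be supplied
through `external_file`.

## Distribution statistics

* Quantiles use linear interpolation between order statistics (R's
  type 7) — the convention is documented because quartile definitions
  differ across software; tests that compare against theory use
  order-statistic confidence bands, not exact quantile identities.
* The pruning trade-off at cutoff `T` reports the removed-conformer
  fraction `Σ #{members with E − E_global > T} / Σ n_conformers` against
  the lost-bound fraction `#{ΔE > T}/n`; both are non-increasing in `T`,
  an asserted property.
* Atom-count bins are half-open: [1,30), [30,40), [40,50), [50,60),
  [60,70), [70,∞) — every record lands in exactly one bin.
* Benchmark metrics compare methods on *relative* energies: each method's
  energies minus its own value on the conformer where the reference
  method is minimal, so per-molecule constant offsets cancel. R² is the
  coefficient of determination about the identity line
  (1 − SS_res/SS_tot), *not* squared Pearson — it can be negative, and
  negative-R² molecules are excluded from aggregates and counted. (A
  squared correlation could never be negative, so the exclusion rule
  itself fixes this reading.) Zero-variance molecules are excluded with a
  reason rather than contributing undefined correlations. Charge
  stratification is a grouping flag over the same metrics, no new
  estimator.

## The synthetic cohort generator

`make_cohort()` is the package's study-conditions generator: it emits
ensemble records with a fully known ground truth, so parameter recovery
is testable end to end. What it emulates, and the frozen constants:

* **ΔE model.** Gamma by default, shape 0.971512 and scale 4.372
  kcal/mol — solved once so the median is 2.91 and the 90th percentile
  9.85 kcal/mol, the scale of strain observed for crystallographic
  ligands. Exponential and lognormal models are available. Draws are
  exact (inverse-transform through a Gaussian copula), and the realized
  per-record ΔE values are retained as ground truth.
* **Size coupling.** A Gaussian copula (rank correlation 0.5) couples
  ΔE to the atom count, whose model is Normal(48.6, 18.6²) truncated at
  8. Larger molecules strain more; the marginal ΔE distribution is
  untouched. The correlation was fixed once against the size-binned
  strain medians observed for crystallographic ligand cohorts and is a
  fixture choice, not an estimate.
* **Ensemble members.** Member energies above the global minimum are
  lognormal(meanlog 3.1289, sdlog 3.5824) — fixed once so the
  heavy-tailed pruning fractions match those of real generated
  ensembles (about 65%/59%/51% of conformers more
  than 6/10/20 kcal/mol above the minimum). Ensemble sizes put roughly
  half the ligands at the 200-conformer cap and almost all above 5.
* **Categories.** With probability ~0.124 a record's bound energy beats
  the ensemble minimum (small negative exponential ΔE), with ~0.220 it
  lies beyond the 20 kcal/mol window, and 2% of records are
  single-conformer (what the multiconformer filter removes); the
  remainder are `within` records. About 9% of records carry a net
  charge.

What it does **not** emulate: real potential-energy surfaces (absolute
energies are arbitrary per-ligand offsets), generator bias and
incomplete conformational coverage, charge-dependent potential errors,
or any geometric realism — records carry energies, not coordinates.
Passing recovery tests on these cohorts therefore demonstrates that the
*statistics* are implemented correctly at realistic scales and shapes,
not that any particular potential reproduces crystallographic strain.

Geometric fixtures come from `make_molecule_fixtures()`: idealized
tetrahedral embeddings of small molecules spanning rigid/flexible,
CHON/CHONSFCl/out-of-set, constitutional-isomer and enantiomer cases.
They are valid clash-free 3D structures for exercising the machinery,
not physical minima.

## The pipeline

`run_pipeline()` chains best-resolution selection (smallest Å value per
ligand, ties to the lexicographically smallest structure id; non-X-ray
ligands dropped and reported), element filtering (CHON or CHONSFCl),
generation, optimization of bound pose and members, identity filtering,
multiconformer filtering, record construction, subset clustering and the
summary artifacts (JSON-lines ledger, filter-report JSON, summary CSVs).
Per-ligand failures are logged and skipped. Reruns are resumable through
the ledger, and all randomness derives from one global seed (per-ligand
seeds are `(seed + 7919·k) mod 2³¹−1`), so a repeated run is
byte-identical — the ledger serializes floating point at 17 significant
digits for exactly this reason.

The default per-ligand potential anchors a committee well at the
ligand's reference geometry, adding a second, torsion-twisted well of
seeded random depth for flexible molecules so that bound and global
conformations can genuinely differ. A ligand entry may carry a separate
`reference` geometry to anchor the potential when the bound pose itself
is displaced from the minimum — as crystallographic poses are.

## Problem sizes and numerical choices

The test suite runs optimizer checks on wells up to 60 Cartesian
dimensions from 100 seeded starts, identity matching on 200 random
permutation fixtures plus brute-force oracle comparisons on graphs of up
to 12 atoms, parameter recovery on 5,000-record cohorts against 99%
order-statistic confidence bands, threshold-trade-off enumeration on 100
random cohorts, and end-to-end determinism on a 50-ligand pipeline run —
sizes chosen to exercise every code path at meaningful statistical power
while keeping the default suite fast. `scripts/acceptance.R` scales the
cohort to 26,395 ligands, the scale at which the distribution statistics
stabilize to two digits.

Remaining numerical choices: soft-minimum temperature 1 kcal/mol;
line-search minimum step 10⁻¹²; duplicate-conformer detection at 10⁻⁶ Å;
energy ties for the global conformation break to the first member in
generation order; the finite-difference step for gradient-free
force-field calculators is 10⁻⁴ Å.

## Known limitations

* The torsion generator does not sample ring conformations or invertible
  nitrogens; molecules whose flexibility is ring-dominated yield small
  ensembles.
* Identity matching is connectivity-based: tautomers and protonation
  states are different molecules by design, and bond-order changes are
  invisible.
* The mock committee potential has constant member spread, so ρ is
  geometry-independent there; real committee spread grows off the
  training manifold.
* `benchmark_metrics()` requires matched conformer ordering between
  methods; it does not attempt conformer re-identification.
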