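---
title: "End-state LIE binding free energies: model, assumptions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{End-state LIE binding free energies: model, assumptions and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nnlie)
```

## The model

`nnlie` post-processes end-state MD trajectories into absolute binding
free energies in the linear interaction energy (LIE) formalism.  Two
physical states are sampled: the solvated protein–ligand complex (PLS)
and the free ligand in water (LS).  For each snapshot the interaction
energy between two atom groups is

$$\Delta E_\mathrm{int} = E(A \cup B) - E(A) - E(B),$$

three single-point evaluations per pair per frame.  Under the additivity
assumption of pairwise-decomposable interactions, the ligand's
interaction with its whole surroundings splits into ligand–protein and
ligand–solvent channels, which is what makes the L–P and L–S terms
separately meaningful.  (For the package's pairwise mock backend this
additivity is exact, and the test suite asserts it to 1e-9 eV; for a
neural-network potential it holds only approximately and is treated as a
modelling assumption, not a tested identity.)

Ensemble averages of these per-frame energies feed linear estimators:

* solvent ignored: $\Delta G = \beta\,\langle\Delta E^{L\text{-}P}_\mathrm{nnp}\rangle + \gamma$,
  optionally $+\,\alpha\,\langle\Delta E^{L\text{-}P}_\mathrm{d3}\rangle$;
* solvent included: each channel's L–P mean is augmented with
  $\langle\Delta E^{L\text{-}S}\rangle_{PLS} - \langle E^{L\text{-}S}\rangle_{LS}$,
  the bound-minus-free ligand–solvent difference;
* classical MM LIE: van der Waals and electrostatic bound-minus-free
  differences scaled by $\alpha$ and $\beta$.

$\alpha$ and $\beta$ are dimensionless, $\gamma$ is in kcal/mol.  The
formalism deliberately omits the linear-response "preorganization"
term, conformational entropy changes, and any continuum-solvent
correction: entropic effects enter only through the width of the
sampled energy distributions, as is conventional for LIE.

A deliberately non-transferable detail: slope coefficients depend on the
unit the x-terms were expressed in during fitting.  `lie_coefficients`
therefore records `units_in`, and the package always converts ensemble
means from eV to kcal/mol *before* applying coefficients, so fitted and
applied conventions cannot silently diverge.

## Backends

All backends implement one contract — a scalar potential energy in eV
for an isolated (non-periodic) cluster — because the LIE bookkeeping
must not care where energies come from.

**`ani2x` (neural-network potential).**  The supported element set
(H, C, N, O, F, S, Cl) and all validation, batching and table plumbing
live in the package; the evaluator itself is supplied by the user as
`params$energy_fn`, since NNP weights are an external artifact with
their own distribution channels.  The contract expects reproducibility
to ~1e-4 eV for a pinned model version; bitwise stability across
hardware is explicitly not promised.  Sodium — a routine neutralising
counter-ion in MD boxes — is outside the element set, which is why the
ion-stripping step exists.

**`dispersion`.**  A table-driven pairwise damped dispersion series,
$E = -\sum_{i<j} [s_6 f_6 C_{6,ij}/r^6 + s_8 f_8 C_{8,ij}/r^8]$ in
atomic units, with per-element diagonal $C_6$ coefficients
(free-atom-like London coefficients) and a per-element multipole ratio
$\rho_i = C_{8,ii}/C_{6,ii}$; off-diagonal terms combine geometrically.
There is no coordination-number interpolation: one fixed coefficient
per element.  That sacrifices some absolute accuracy but keeps the
backend deterministic, dependency-free and cheap, which is the right
trade-off for a term that enters the estimators only through a fitted
scale factor $\alpha$.  Both rational Becke–Johnson damping (default:
$s_6 = 1$, $s_8 = 0.2641$, $a_1 = 0$, $a_2 = 5.4959$ Bohr, a published
ωB97X-compatible set) and zero damping ($sr_6 = 1.281$, $sr_8 = 1.094$)
are available because force-field-era conventions differ; the choice is
recorded in run summaries.

**`mock`.**  Lennard-Jones + Coulomb with Lorentz–Berthelot combination
and $k_e = 14.399645$ eV·Å·e⁻²; parameters are a fixed per-element
table published in the source (organics neutral, alkali ions +1).  Its
purpose is to be *exactly* brute-forceable: the cross-group pair sum is
a closed-form oracle against which the whole pipeline is verified.

## Parameters that matter

| Parameter | Default | Unit | Why |
|---|---|---|---|
| solvation cutoff | 4.0 | Å | waters beyond a thin shell around the buried ligand contribute negligibly to L–S, and shell reduction bounds evaluator cost; the shell is measured from the whole PL complex (a ligand-only mode exists) |
| distance metric | min atom–atom | Å | the most conservative reading of "nearest waters"; hydrogens included |
| uncertainty estimator | sem | eV | plain iid standard error of the ensemble mean; `sd` available; no autocorrelation correction (frames are assumed decorrelated by the export stride) |
| eV→kcal/mol | 23.060548 | — | fixed CODATA-derived constant; printed conversions elsewhere sometimes round inconsistently, so one constant is pinned and logged |
| temperature for RT·ln K | 298.15 | K | thermochemical standard; pass 310 K to match body-temperature MD protocols |
| test fraction / splits | 0.1 / 100 | — | the conventional 90/10 × 100 random-split protocol; with n = 54 this gives 48 train / 6 test (`ceiling`, so the test set never rounds to empty-ish 5) |
| mm defaults (α, β, γ) | 0.181, 0.5, 0 | — | the conventional classical-LIE defaults; refitting to the studied series is expected |

## Numerical and procedural choices

* **Convergence subsampling** uses the first frame of each of *n* equal
  intervals over the reference window (`floor(k·N/n)+1`), a fixed,
  RNG-free rule, so deviation-versus-frames profiles are exactly
  reproducible.
* **Cross-validation** seeds one RNG stream and draws all test sets
  up front; identical seeds give identical splits and results.
* **OLS fitting** goes through a QR decomposition with an explicit
  rank check; standard errors come from the OLS covariance.  Degenerate
  designs (collinear predictors, too few points) are errors, not
  warnings.
* **Index handling**: `.ndx` indices are 1-based (Gromacs convention)
  and interpreted as atom *serials* throughout, so group selections
  remain valid on frames reduced by ion stripping or shell reduction,
  which preserve serials.
* **Element inference** (when the PDB element column is blank): strip
  digits, prefer the two-letter symbol, except inside standard amino
  acids where names like "HG" resolve to hydrogen.
* **PBC**: frames are assumed whole and centered (imaging is an
  upstream, trajectory-tool job).  The reader only warns when an
  intramolecular nearest-neighbour distance exceeds 5 Å — the symptom
  of a broken molecule.  No minimum-image convention anywhere.
* **Fail-loud stripping**: an unsupported element in a strippable ion
  residue is removed; the same element in a ligand or protein is a hard
  error, because silently dropping a ligand atom would corrupt ΔE.
* **Frame times** are `frame_index × time_per_frame`, since exported
  PDBs rarely carry trustworthy time stamps.

## What the synthetic fixtures do and do not show

`make_toy_trajectory` builds a rigid receptor cluster, a small ligand
3–5 Å off its surface, whole TIP3P-like waters packed outside the
solute, optional sodium ions, and seeded Gaussian jitter across frames
(defaults: 24 receptor atoms, 8 ligand atoms, 20 waters, 3 frames,
0.05 Å jitter).  `make_synthetic_lie_dataset` draws ensemble means
uniformly from −90 to −20 kcal/mol — the realistic ligand–protein
interaction range — and adds Gaussian noise to a generating line
(defaults β\* = 0.106, γ\* = −5, σ = 1.5 kcal/mol, n = 54, matching the
scale of a multi-family benchmark study of CoV/HIV-1/JNK protease–ligand
complexes).

These fixtures validate *plumbing and arithmetic*: parsers, extraction,
oracle equality of interaction energies, shell reduction, estimator
algebra, fitting and cross-validation protocol.  They do not emulate
real protein geometry, water structure, conformational sampling or NNP
accuracy.  Consequently a green test suite demonstrates that the
pipeline computes what it claims to compute — not that any particular
accuracy against experiment will be achieved on real systems, which
depends on trajectory quality and the chosen evaluator.  Reproducing a
published-scale benchmark (dozens of complexes × ~100 frames with an
NNP) requires the original trajectories and model and is out of desk
scale by design; the test suite instead runs the identical fit and
90/10 × 100 cross-validation protocol on the synthetic study.

Problem sizes in the shipped tests and acceptance script — toy systems
of 12–24 receptor atoms with 4–20 waters, 20 oracle systems, 100
fitting replicates of n = 54 — were chosen so the whole suite runs in
seconds while every code path, including the quadratic brute-force
oracles, is exercised.

## Known limitations

* No force/gradient evaluation, geometry optimization, or NNP training.
* No binary trajectory formats (XTC/TRR/DCD): convert to multi-model
  PDB or per-frame PDBs first.
* No autocorrelation-aware error bars; sem assumes independent frames.
* The dispersion backend's fixed per-element coefficients are not a
  substitute for a full coordination-number-dependent D3 when absolute
  dispersion energies matter; here it only feeds a fitted linear term.
* Coefficients fitted on one unit convention, protein family or
  evaluator do not transfer silently; refit for new series.
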