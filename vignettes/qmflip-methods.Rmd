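---
title: "Assigning histidine protonation by quantum-mechanical flipping"
author: "qmflip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assigning histidine protonation by quantum-mechanical flipping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qmflip)
```

## The problem

The imidazole ring of histidine can carry a hydrogen on ND1, on NE2, or on
both (the positively charged imidazolium). X-ray crystallography at typical
resolution cannot see these hydrogens, and the near-symmetry of the ring
means the refined model may also have the ring flipped 180° about the
χ~2~ axis. That leaves six candidate configurations per histidine:
three protonation states, each unflipped or flipped.

`qmflip` decides among the six by physics rather than by library
statistics: each configuration is geometry-minimized inside its frozen
molecular environment and the minimized energies are compared, after a
correction that makes configurations with different proton counts
comparable. Because the procedure relies only on atomic positions, it is
applicable wherever the local model is trustworthy — at low resolution, near
metals, and next to ligands, where purely empirical hydrogen-placement
tools may lack parameters.

## The cluster

`selectCluster()` excises a quantum-chemistry micro-model around the target
histidine: every entity (residue, water, metal, ligand) with at least one
atom within a buffer distance — default 3.5 Å — of any histidine atom is
included whole. `capCluster()` replaces severed backbone peptide bonds with
hydrogens placed exactly on the severed bond vector (N–H 1.01 Å, C–H
1.09 Å) and gives bare waters their two hydrogens (0.96 Å, 104.5°).
`assignFreezeFlags()` then freezes environment heavy atoms; all hydrogens,
all caps and the histidine are free, except the histidine stem CA–CB–CG,
which stays frozen so the ring remains anchored at its experimentally
observed attachment point.

The net cluster charge sums textbook formal charges at physiological pH
(Asp/Glu −1, Lys/Arg +1, metals from a small lookup) with the target
histidine counted in its doubly protonated +1 reference state; singly
protonated configurations subtract one. Crystal-symmetry neighbours are
*not* generated; when a unit cell is present and the site lies within
buffer + 5 Å of a cell boundary the package warns that symmetry contacts
are missing rather than silently ignoring them.

## The six configurations and the planar restraint

`enumerateConfigurations()` produces, in canonical order, HD1^HE2, HD1,
HE2 and their three flipped counterparts. Ring nitrogen protons present on
input are discarded and rebuilt (1.01 Å, in-plane, along the external
bisector of the ring angle), so all six states start from identical heavy
atoms. The flip is implemented literally as the coordinate swap
ND1↔CD2, CE1↔NE2 — not as a rigid χ~2~ rotation — which preserves the
experimental ring atom positions exactly; for an ideal planar ring the two
operations coincide.

Unconstrained minimization of a *wrong* protonation can rotate the ring
into a spurious pose that partially hides the clash. Each configuration
therefore carries a harmonic restraint on the CA–CB–CG–ND1 torsion with
its target set to the value measured on that configuration's own starting
geometry. The functional form and weight are this package's reading of
"restrain the ring plane towards the main chain": harmonic, default weight
50 kcal mol⁻¹ rad⁻² (≈0.0152 kcal mol⁻¹ deg⁻²), exposed as
`restraintWeight` and switchable with `restrain = FALSE`. On a fixture
with a deliberate clash against a ring proton, the restrained torsion
stays within a degree of its start while the unrestrained one drifts by
tens of degrees — the qualitative contrast the restraint exists to produce.

## Energies: calibration, proton reference, threshold

Semi-empirical heats of formation are directly comparable only at equal
atom and electron counts; the imidazolium states have one proton more than
the tautomers. The package bridges them with a linear pKa model

$$\mathrm{p}K_a = a + b\,[G(\mathrm{A}^-) - G(\mathrm{HA})]$$

fitted by ordinary least squares (which minimizes the RMS pKa error) to
the bundled table of 20 experimental pKa values with PM6-D3H4/COSMO
(ε = 78.4) heat-of-formation differences, spanning both N- and O-bound
protons. The fit gives a = 42.180, b = 0.368 mol kcal⁻¹ and an RMS error
of 1.77 pKa units (n − 2 denominator; the 1/n convention gives 1.68,
which does not match the quoted error, so n − 2 is used deliberately).

The effective free energy of a solvated proton balances protonated and
deprotonated forms when the pKa equals the pH:

$$G(\mathrm{H}^+) = \frac{\mathrm{pH} - a}{b},$$

−94.51 kcal mol⁻¹ at pH 7.4 for the all-data fit (−94.72 for the
N-subset, −93.88 for the O-subset). `comparableEnergy()` subtracts
G(H⁺) once per missing proton, counted against the maximally protonated
configuration, which fixes the sign convention unambiguously.

One convention deserves emphasis: the published reference constants derive
from the fit coefficients *quoted at their printed precision* (a to two
decimals, b to three). `printedPrecision()` applies exactly that
quantization, and with it the package reproduces the published model-pKa
column and all three proton references to the last printed digit; the
full-precision fit differs by up to ≈0.09 kcal mol⁻¹ in the N-subset
reference. Both fits are available; defaults use the quantized one so
reported constants match the published calibration.

The RMS error of the fit translates to an energy resolution of
rms/b = 4.81 kcal mol⁻¹. Energy gaps below this threshold cannot reliably
order two states, so every such state is reported in the ambiguity set
rather than silently dropped: a 2.6 kcal mol⁻¹ gap between imidazolium and
HD1 means "either is acceptable", not "imidazolium loses".

## Backends

The QM engine is always external. The MOPAC adapter writes an input deck
(method token, `EPS=78.4`, `CHARGE=n`, per-coordinate 0/1 optimization
flags), drives the executable, and parses the final heat of formation and
Cartesian block; abnormal termination is reported as a non-converged
result, never an exception. When no MOPAC executable is on the PATH the
pipeline falls back, with a loud warning, to the built-in surrogate.

The surrogate is a deterministic molecular-mechanics-style energy —
harmonic bonds (ideal lengths from a small element-pair table) and angles
(reference values from the starting geometry), Lennard-Jones with
near-zero radii on polar hydrogens, Coulomb with a distance-dependent
dielectric, an angular 10–12 hydrogen-bond well, and the torsion
restraint. Every hydrogen additionally carries a constant formation term
equal to minus the aqueous proton reference, so removing a non-interacting
proton changes the raw energy by exactly G(H⁺) and the downstream
correction cancels — the property the real calibration achieves for
PM6-D3H4. Its constants are shipped, fixed, and make no claim to chemical
accuracy: the surrogate exists so ordering, restraint mechanics,
freeze-flag conservation and report plumbing are testable bit-for-bit with
no QM engine installed. Minimization runs cycles of L-BFGS-B over the free
coordinates only (frozen atoms are excluded from the parameter vector, so
their coordinates are preserved exactly), with a central-difference
gradient, convergence at a 10⁻⁴ kcal mol⁻¹ Å⁻¹ gradient or a 10⁻⁷
energy change, and a recorded, non-increasing energy trace. There is no
randomness anywhere in the pipeline: reports are reproducible by
construction.

## Metrics and the decision

Each minimized configuration is scored by three metrics. Hydrogen bonds
are counted with conventional geometric criteria (D···A ≤ 3.5 Å,
H···A ≤ 2.5 Å, D–H···A ≥ 120°, configurable), each hydrogen counting at
most once, restricted to bonds involving at least one atom that was free
during minimization. The RMSD from the configuration's own starting
geometry (for flipped states, the post-swap coordinates) flags poses that
had to move far to relieve a clash. The rotamer label bins χ~1~ to
p/t/m and appends χ~2~ rounded to 10°, with OUTLIER beyond 40° of every
bin centre — a sanity label, deliberately not a full rotamer-library
lookup.

`runQMF()` assembles the report: proton-corrected energies, ΔE against
the minimum, the winning state (ties break by canonical order, so reports
are deterministic), and the ambiguity set under the 4.81 kcal mol⁻¹
threshold. `runQMFAll()` processes every histidine independently; its
`iterate = TRUE` mode re-runs sites in increasing energy-gap order,
rebuilding each called histidine into the environment before the next
site, for at most three sweeps or until stable — a bounded version of the
"correct each histidine, then revisit" refinement the independent-site
approximation suggests.

## What the synthetic fixtures do and do not show

The fixture generator builds an Ace–His–Nme fragment (optionally with
flanking glycines to exercise peptide capping) from a shipped
internal-coordinate table — ring angles nudged by under a degree from
library ideals so the five-membered ring closes exactly on its tabulated
bond lengths — with requested χ~1~/χ~2~, plus partners placed along the
ring nitrogens' in-plane interaction vectors: a carbonyl probe (acceptor
only), an ammonia probe (donor only), water in either orientation, or a
bare clash atom. Partner probes are synthetic constructions, named as
such.

Passing tests on these fixtures demonstrate that the machinery is correct:
selection matches a brute-force distance scan, caps sit on their severed
bonds to 10⁻⁶ Å, frozen atoms never move, the restraint holds the plane,
an acceptor planted against the HD1 proton elects an HD1-bearing state and
a donor planted there elects HE2. They do not demonstrate chemical
accuracy on real crystal structures: reproducing published absolute heats
of formation and the metal/ligand case studies requires a licensed QM
engine and structure downloads, and is deliberately out of scope.
Problem sizes in the shipped tests are small by design — clusters of
15–30 atoms, minimizations of a few dozen degrees of freedom, 100-trial
hydrogen-bond comparisons and 200-replicate calibration recoveries — which
keeps the whole suite in the minutes range while exercising every code
path.

## Numerical choices and limitations

* Only the blank/'A' alternate conformer is processed; alternates are
  dropped with a warning. The method operates on a single conformer.
* Ties at the energy minimum break by canonical state order; exact ties
  essentially never occur with real energies.
* Environment protonation beyond waters is the user's responsibility
  (edit the model to test a what-if, e.g. a protonated aspartate, then
  re-run).
* Asn/Gln flips, D-histidine and ligand imidazoles are out of scope; the
  building blocks (cluster extraction, minimization, corrected
  comparison) can be driven manually for such cases.
* Metal formal charges and spin states come from a small lookup and are
  user-overridable in principle via the cluster's net charge; the default
  is the common oxidation state.
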