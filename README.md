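# qmflip

Histidine protonation assignment for macromolecular models by
quantum-mechanical flipping.

## The problem

A histidine imidazole can be protonated on ND1, on NE2, or on both (the
+1 imidazolium), and the near-symmetric ring may additionally be flipped
180° about χ₂ — six candidate configurations that X-ray data at typical
resolution cannot distinguish, because the hydrogens are invisible and the
N/C ring atoms scatter almost identically. Getting the choice wrong
corrupts hydrogen-bond networks, metal coordination and ligand
interactions in the refined model.

`qmflip` decides among the six configurations with energies rather than
empirical rules. Around the target histidine it excises a small cluster
(every entity within a buffer distance, default 3.5 Å, severed peptide
bonds capped with hydrogens, environment heavy atoms frozen), enumerates
the six protonation/flip states, geometry-minimizes each with a planar
torsion restraint anchoring the ring to the main chain, and compares the
minimized energies. States that differ by a proton are made comparable by
the linear pKa calibration

    pKa = a + b · [G(A⁻) − G(HA)],      G(H⁺) = (pH − a)/b

fitted to a bundled table of 20 experimental pKa values with
semi-empirical (PM6-D3H4, COSMO ε = 78.4) heat-of-formation differences:
a = 42.18, b = 0.368 mol kcal⁻¹, RMS error 1.77 pKa units, giving
G(H⁺) = −94.51 kcal mol⁻¹ at pH 7.4 and a significance threshold of
rms/b = 4.81 kcal mol⁻¹ below which two states cannot be reliably
ordered. Each configuration is additionally scored by hydrogen-bond
count, RMSD from its starting geometry, and rotamer label.

Energy minimization runs through a pluggable backend: an adapter for the
external MOPAC program (input writer, output parser, subprocess driver),
or a built-in deterministic surrogate energy model so that the entire
pipeline — and its test suite — runs with no QM engine installed.

## A worked example

The package ships a synthetic micro-environment generator, so a complete
run needs no input files. Here an ammonia probe donates a hydrogen bond
into ND1, which should force the ring nitrogen to stay unprotonated —
i.e. the HE2 tautomer:

```r
library(qmflip)

s    <- fixturePreset("donor-at-ND1")   # Ace-His-Nme + NH3 donor at ND1
site <- findHistidines(s)[[1]]
rep  <- runQMF(s, site)                 # surrogate backend
rep
```

```
His 2 A  (pH 7.4, threshold 4.81 kcal/mol)
Configuration            Energy       dE H-bonds    RMSD  Rotamer
0 unknown                                                     m90
1 HD1, HE2                666.1      5.1       0    0.38      m90 
2 HD1 only                666.1      5.1       0    0.46      m90 
3 HE2 only                661.0      0.0       1    0.54      m90 
4 HD1, HE2 flipped        662.8      1.8       0    0.40     m-90 
5 HD1 only flipped        662.6      1.6       0    0.39     m-90 
6 HE2 only flipped        664.1      3.1       0    0.37     m-90 
Call: HE2
Ambiguous with: HD1, HE2 flipped; HD1 only flipped; HE2 only flipped
```

Line 0 is the input model (here without ring protons, rotamer m90). Each
numbered line is one configuration: its proton-corrected energy
(kcal mol⁻¹, surrogate scale), the gap ΔE to the best state, hydrogen
bonds in the minimized geometry, RMSD from that configuration's starting
coordinates, and rotamer. HE2 wins — it alone accepts the probe's
hydrogen bond — and the two HD1-bearing unflipped states sit 5.1 kcal/mol
up, just beyond the 4.81 significance threshold; states within the
threshold are listed as ambiguous rather than rejected.

For real models: `s <- readPDB("model.pdb")`, pick a site with
`hisSite(s, "A", 4)` or all of them with `runQMFAll(s)`, choose
`backend = "mopac"` when a MOPAC executable is on the PATH, and export
with `reportJSON()` / `formatReport()`. A thin shell front-end is
installed at `inst/scripts/qmflip` (`qmflip run model.pdb --his A:4`,
`qmflip fixture --preset bare --out f.pdb`, `qmflip calibrate`).

The calibration itself is exposed directly:

```r
fit <- printedPrecision(fitPkaModel(pkaReferenceData()))
modelPka(fit, -97.80)                     # 6.19  (histidine)
gProton(protonFreeEnergy(fit, 7.4))       # -94.51 kcal/mol
energyThreshold(fit)                      # 4.81  kcal/mol
```

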