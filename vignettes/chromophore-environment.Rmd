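---
title: "Mapping the chromophore microenvironment of fluorescent proteins"
author: "fpchrom"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping the chromophore microenvironment of fluorescent proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fpchrom)
```

## The problem

The photophysics of GFP-family fluorescent proteins — brightness, quantum
yield and especially fluorescence lifetime — is governed by the immediate
surroundings of the tripeptide-derived chromophore buried in the
beta-barrel.  Comparing a mutant with its precursor therefore comes down to
a set of concrete geometric and statistical measurements: which residues
form the chromophore's nearest shell, which of them hydrogen-bond to it
(directly or through ordered waters), how tightly the hydrophobic lining
packs, how a dimer interface is stitched together, how mobile the pocket
residues are in solution, how long individual contacts live, and which
electrostatic states the chromophore populates.  `fpchrom` implements this
measurement layer: static analyses on crystal structures and ensemble
analyses on conformational ensembles, with a synthetic generator that
provides exact ground truth for every stage.

## Static structure analyses

**Containers.** `readPDB()` parses fixed-column PDB records (delegating the
format plumbing to `bio3d`) into an `FPStructure`, a validated atom table in
file order.  Alternate locations default to the highest-occupancy conformer
(ties resolved toward blank/'A'), because all downstream geometry assumes a
single conformer; the policy is recorded in the object's metadata.
Residue numbering follows the file verbatim, waters are retained as `HOH`,
and no symmetry expansion is performed — deposited files for these proteins
already contain all chains of interest.

**Hydrogen bonds.** Crystal structures of this resolution class carry no
hydrogens, so the static criterion is heavy-atom based: a donor-capable and
an acceptor-capable polar atom within a distance cutoff.  Capability comes
from a residue/atom lookup (backbone N donates, backbone O accepts,
hydroxyls, histidine ring nitrogens and waters are ambivalent; Cys/Met
sulfur can be enabled as a weak acceptor but is off by default).  No
donor-angle term is applied in static mode — a known limitation of
hydrogen-free structures, stated rather than papered over.  The default
cutoff is 3.3 Å for chromophore-shell work, the conventional figure-caption
criterion; the dimer-interface default is 3.7 Å because published interface
tables conventionally admit long polar contacts near 3.6 Å.  Both are
arguments, not constants.

**Water-mediated bonds** are bridges: a chromophore polar atom and a
residue polar atom each within the H-bond cutoff of the same water oxygen.

**Hydrophobic contacts** pair apolar carbons (carbons not covalently bonded
to N or O, tabulated per residue type) at ≤ 4.0 Å, a conventional van der
Waals contact distance; results are aggregated per residue.

**The shell census** (`shellCensus()`) lists residues with any heavy atom
within a radius (default 4 Å) of any chromophore heavy atom, then labels
members using the three detectors.  Two deliberate choices: (i) the
chromophore's covalent neighbours enter the shell only through genuinely
non-bonded atoms — the splice backbone atoms (predecessor C/O, successor N)
are excluded from the distance test, and the rule is echoed in the report;
(ii) shell members matching no detector are reported as *unclassified*
rather than forced into a class, because a 4 Å neighbour can be real and
load-bearing without satisfying any of the three criteria.

**Dimer interfaces.** Buried area is computed as
SASA(A) + SASA(B) − SASA(A∪B) with a hand-written Shrake–Rupley sampler
(Fibonacci sphere points, element radii C 1.70 / N 1.55 / O 1.52 / S 1.80 Å,
probe 1.4 Å); the total over both subunits is reported, with a
`halfArea` flag for the one-sided convention.  Interface H-bond counting
follows the crystallographic two-fold convention: detected cross-chain
bonds are reduced to unique residue/atom-pair labels; under symmetry
doubling each label counts twice except a label symmetric under swapping
its two sides, which counts once.  Doubling is a *reporting* convention —
the structure's own second copy of a bond may deviate from perfect
symmetry, so detection always happens on the unique list.

**Geometry.** Superposition is a standard Kabsch fit (SVD with determinant
correction); the mutant-vs-precursor probe displacement (`atomShift()`)
defaults to a whole-monomer C-alpha fit, which isolates side-chain and
chromophore movements from lattice differences.  Whether such a shift is
better measured after a local-site fit is genuinely open; both are
available through `fitSelection`, with whole-monomer as default.  Ring
planes are least-squares planes (smallest principal direction); plane
angles use the acute convention.  The histidine-to-hydroxyl measurement is
operationalized as the minimum over \{ND1, NE2\} because published
distances of this kind rarely name the atom.

## Ensemble analyses

**RMSF.** Frames (after discarding an initial equilibration fraction,
default 25% so that the final three quarters of the ensemble are analysed)
are Kabsch-fitted to the ensemble mean on a fit selection (default
C-alpha), and per-atom RMSF is the root mean squared deviation from the
mean position.  Per-residue values average side-chain heavy atoms by
default — pocket flexibility is a side-chain story — falling back to all
heavy atoms for glycine-like residues.  Note that fitting on a small atom
subset leaks fit jitter of order σ/√N_fit into all atoms; parameter-recovery
experiments therefore fit on the full atom set.

**Contact occupancy.** With explicit hydrogens the per-frame criterion is
donor–acceptor ≤ 3.5 Å *and* H–donor–acceptor angle ≤ 30°, the common MD
convention; without hydrogens it falls back to the heavy-atom 3.3 Å rule.
PrOc is the exact fraction of present frames; lifetimes are maximal runs of
consecutive presence times the frame spacing, and the bookkeeping conserves
mass (sum of event lengths equals total present frames, an invariant the
tests assert exactly).  The group-level "interactions per unit time" is
implemented as the mean count per frame, the reading that is dimensionally
consistent with values like 3.6 bonds.

**π–π stacking** uses centroid distance ≤ 5.5 Å and inter-plane angle
≤ 30°.  No universal criterion exists, so the result carries a sensitivity
report (PrOc at ±0.5 Å) and both thresholds are arguments.

**Dipole moment.** The chromophore fragment (imidazolinone ring,
aryl-alkene bridge, phenol ring, carbonyl and hydroxyl oxygens, hydroxyl
proton when present) gets DM = Σ qᵢ(rᵢ − r_ref), converted at
1 e·Å = 4.8032 D.  Because the fragment may carry net charge, the dipole is
origin-dependent and the reference point is part of the contract: the
default is the fragment's per-frame heavy-atom centroid, always echoed on
the result, and the neutral-fragment origin-independence is tested to
1e-9 D.  Published absolute moduli for charged fragments are therefore only
comparable under the same convention — which published work often leaves
unstated.  Orientation is the angle to the CG2→CZ phenol axis in the
vector convention [0°, 180°].

**Two-state classification.** The phenolic proton's cis/trans configuration
with respect to the imidazolinone carbonyl oxygen is classified per frame
from the angle between the O→H vector and the O→carbonyl-O vector,
binarized at 90°.  Without a hydroxyl hydrogen in the topology the frames
are *not* classified — no heavy-atom proxy is silently substituted, since
any such proxy would encode exactly the assumption under test.

## The synthetic generator

`toyShellStructure()` builds a mini-protein around a CRO-named chromophore
whose pocket composition mirrors the canonical GFP arrangement: 5 direct
H-bond serines at staggered distances (2.8–3.2 Å), 2 bridging waters
serving 6 serines, 7 hydrophobic leucines at 3.8 Å, and one unclassified
glycine — 19 shell residues at 4 Å.  Placements are exact: each contact
atom sits at its target minimum distance to 0.01 Å, and the construction
errors out rather than deliver an off-target pocket.  The imidazolinone
plane is tilted 7° from the phenol plane, the near-coplanarity typical of
an intact chromophore.

`makeEnsemble()` layers three independent stochastic mechanisms on a base
structure, all under one seed:

* i.i.d. Gaussian positional noise per atom (default σ = 0.30 Å per
  coordinate, a mid-range side-chain fluctuation amplitude, giving the
  closed-form per-atom RMSF σ√3 ≈ 0.52 Å);
* two-state Markov switching of named contacts at a specified stationary
  occupancy and mean on-dwell, realized by moving only the acceptor along
  the donor–acceptor axis between 2.9 Å (on) and 4.5 Å (off).  Atoms in
  switched contacts get σ = 0 unless overridden, so the Markov chain is the
  only source of variation in that distance — noise would otherwise blur
  the on/off states and the recovered occupancy would measure the noise,
  not the chain;
* i.i.d. cis/trans switching of the hydroxyl proton between its two
  in-plane rotamer positions at a specified trans fraction (the hydroxyl
  group likewise gets σ = 0 by default).

The manifest records every realized per-frame label, realized occupancy and
dwell, per-atom σ with the implied RMSF, and the noise-free dipole state
centers, so analysis output is checked against ground truth without
rerunning the generator; identical seeds reproduce everything bit for bit
(the caller's RNG stream is saved and restored).

What the generator does *not* emulate — and hence what passing tests do and
do not show: noise is uncorrelated in time (no autocorrelation, no
collective motions), contacts toggle geometrically rather than thermally,
there is no solvent, and the toy pocket has no barrel.  Recovery tests
validate the *estimators* (detection, counting, lifetime and population
bookkeeping, fitting), not the physics of any particular protein; analyses
of real ensembles inherit all caveats of the simulations that produced
them.

## Problem sizes and numerical choices

Parameter-recovery experiments use 5,000 frames for RMSF (closed form
recovered within 2%), 20,000 frames for Markov occupancy (±0.02) and dwell
(±10%), and 10,000 frames for state populations (±0.02) — sizes at which
the statistical error of each estimator sits comfortably inside its
tolerance.  SASA uses 240 sphere points per atom by default; doubling the
density moves totals by < 0.5% (asserted), and the lone-sphere closed form
4π(r+probe)² is reproduced exactly in the limit of an isolated atom.
Plane fits reject collinear input; superposition requires ≥ 3 paired,
non-collinear atoms and reports dropped pairs rather than guessing a
mapping.  All degree values are reported in degrees, distances in Å,
lifetimes in ps, dipoles in Debye.

## Limitations

* Static H-bond detection is distance-only; directional chemistry
  (bifurcation, angle quality) is out of scope without hydrogens.
* CH···O and halogen bonds are not considered.
* Buried area is geometric; no interface energetics.
* The ensemble reader supports multi-MODEL PDB and a simple XYZ-per-frame
  dialect; binary MD trajectory formats are out of scope — convert
  externally.
* Measurements on deposited crystal structures require the user to supply
  the PDB files; the package ships only generated fixtures.
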