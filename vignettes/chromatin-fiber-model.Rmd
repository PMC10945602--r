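---
title: "Mesoscale chromatin Monte Carlo with implicit TF bridging: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mesoscale chromatin Monte Carlo with implicit TF bridging: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(chromoMC)
```

## The model

chromoMC represents a chromatin fiber at nucleosome resolution. Each
nucleosome core is a rigid body: a sphere of radius 5.5 nm for excluded
volume, an orthonormal orientation triad, a set of point charges buried just
under the surface that carry the core's net effective charge, and fixed
attachment points where linker DNA enters and exits. Linker DNA is a
bead-spring worm-like chain at ~9 bp (3.06 nm) per bead. Histone tails are
short flexible bead chains anchored on the core surface; linker histones
(LH), when present, are positively charged bead chains anchored on the dyad
bisector between the DNA entry and exit arms, where their electrostatic pull
on both linker arms forms the stem motif that rigidifies and compacts the
fiber.

The potential energy is a sum of ten terms: linker-DNA stretching, bending,
and twisting (`ES`, `EB`, `ET`); tail stretching and bending (`EtS`, `EtB`);
LH stretching and bending (`ElhS`, `ElhB`); excluded volume (`EV`); screened
Debye-Hückel electrostatics (`EC`); and the TF-restraint term (`ETF`). All
harmonic terms use the convention `E = k (x - x0)^2` and vanish exactly at
their reference geometry. Excluded volume is a purely repulsive
shifted-truncated 12-6 potential that is exactly zero at contact
(continuous at the cutoff) and climbs steeply inside; electrostatics use
effective (salt-renormalized) charges with the Debye length set by the
monovalent salt concentration (0.785 nm at the default 0.15 M, 293 K).
Nonbonded interactions are truncated at 12 nm, far beyond the Debye length.

### Implicit TF bridging

A bivalent transcription-factor heterotetramer (the Myc:Max paradigm) is
modeled implicitly. Linker beads can be marked *TF-bindable*, either as
region patterns (consecutive-nucleosome binding regions) or as a bulk
concentration (a percentage of linker beads, sampled with a nested scheme so
higher concentrations are supersets of lower ones at a fixed seed). During a
simulation, two bindable beads **engage** a harmonic restraint
`E = k (l - l0)^2` with `k = 20` kcal/mol/nm² and rest length `l0 = 13` nm
when they come within the 20 nm capture radius while being at least 30
linker beads apart along the chain; a pair that separates beyond 20 nm is
**released**. Each bead holds at most one restraint — the heterotetramer has
exactly two DNA-binding surfaces — and when several pairings are possible
the closest pair engages first (ties broken by lower bead index). Restraint
updates run after every accepted move that displaces a bindable bead, plus a
full refresh every 1,000 steps. The restraint energy is part of the total
used in the Metropolis rule for spatial moves; it is small relative to the
total system energy, and engagement/release themselves are rule events, not
sampled moves.

## Sampling

Configurations are sampled by Metropolis Monte Carlo with five move kinds:

* **global pivot** — the fiber end with fewer cores is rigidly rotated
  about a random axis through a random linker bead;
* **local translations** of single linker beads and LH beads;
* **core moves** — rigid translation or rotation of a nucleosome unit
  (core, surface charges, attachments, tails, and LH ride along);
* **tail regrowth** — configurational-bias (Rosenbluth) bead-by-bead
  regrowth of one tail with 8 trial directions per bead, preserving bond
  lengths; accepted on the Rosenbluth weight ratio.

Move-selection weights are proportional to component counts with a pivot
probability of 0.2; amplitudes default to values measured to give roughly
20–40% acceptance on 25–50 nucleosome fibers (0.5 nm bead displacements,
0.6 nm / 12° core moves, 30° pivots). Tail-state swaps between the extended
and folded reference geometries are exposed as an operation
(`swapTailState`, accepted on the local electrostatic change) but are not
part of the default move mix because the acetylation state is fixed per
system.

Replicas start from an ideal two-start zigzag (alternating ±150° wedge)
built so that every bonded term is exactly zero; the replica's global twist
offset (0, +12, or −12°) rotates each successive core frame about the
preceding linker axis, giving offset replicas distinct initial folds. The
twist registry itself is harmonically tied to the offset and is not
perturbed by the default move set, so `ET` stays at its reference; the
offsets act through the initial geometry, which is their intended role of
mimicking natural twist variation. Energies are tracked incrementally with
a full recomputation at every saved frame (drift is monitored and has been
at machine precision in testing); a non-finite total aborts the run with a
diagnostic.

## Force-field parameters

All defaults are overridable through `defaultForceField()` or the
`forcefield:` section of a YAML run configuration.

| parameter | default | why |
|---|---|---|
| DNA stretch | 30 kcal/mol/nm² | bond-length SD ≈ 0.1 nm at 293 K |
| DNA bend | 4.76 kcal/mol/rad² | 50 nm persistence length at 3.06 nm/bead |
| DNA twist | 7.14 kcal/mol/rad² | 75 nm torsional persistence |
| linker bead charge | −4 e | effective charge of 9 bp after counterion screening |
| core charge | −40 e over 12 sites | net effective core charge; anisotropic screened field |
| tail bead charge | +1 e | weakly basic 5-residue beads; ~1 kBT adhesion wells |
| LH bead charges | +3, +4, +4 e | strongly basic CTD; ~2–3 kBT per linker-arm contact |
| EV diameters | 11 / 2.4 / 1.8 / 2.2 nm | core / DNA / tail / LH effective sizes |
| acetylation multiplier | 100 | folded rigid tails; stiffness × 100 |
| salt | 0.15 M | physiological monovalent salt (λ_D = 0.785 nm) |

The charge magnitudes are deliberately *effective* values chosen once so
that tail-core and LH-DNA contact wells sit at roughly 1–3 kBT: strong
enough for tail-mediated internucleosome attraction and LH stem formation
to emerge, weak enough that Metropolis sampling does not freeze into the
first collapsed state. The core surface charges sit at 0.75 of the core
radius so no approaching bead can fall into an unscreened point-charge
singularity.

Tails default to 4 chains × 3 beads per core and LH to 3 beads — a coarser
resolution than all-residue mesoscale force fields use. This is the
package's resolution choice for desk-scale work: the qualitative mechanisms
(tail bridging, LH stems, acetylation stiffening) are preserved while a
50-nucleosome fiber stays under ~1,500 interaction sites.

## Fibers and genomic tracks

`buildUniformFiber(n, linkerBp)` discretizes each linker to
`round(bp / 9)` beads (minimum 1); `buildLifelikeFiber()` draws per-linker
lengths from the mESC distribution (30% 26 bp, 17% 35, 15% 44, 13% 53,
9% 62, 7% 70, 9% 80). `buildGeneFiber()` tiles a genomic region around
nucleosome-free regions (NFRs): NFR intervals become runs of free DNA beads
with no core; cores are allocated to the inter-NFR segments by largest
remainder; drawn linkers are rescaled so each segment is filled exactly
(the remainder of the NRL arithmetic is absorbed into linkers, which is why
the bundled Eed-like locus can pin 129 cores in a 24.6 kb non-NFR sequence).
Genomic coordinates follow the 0-based half-open BED convention; the
1-based inclusive coordinates common in genome browsers are converted on
ingest.

The bundled Eed-locus fixture is **synthetic**: the region span
(26,322 bp), the NFR count and sizes (two ~350 bp, five ~200 bp), the two
TF-binding intervals, the NRL (189 bp), the pinned core count (129), and
the LH density (0.364 ≈ 0.37) reproduce published summary statistics, but
the NFR positions within the region and the LH peak positions are a
deterministic design choice, not processed sequencing data. One of the TF
intervals extends past the region end in its source coordinates and is
clipped at the region boundary. Conclusions that depend on exact genomic
placement should not be drawn from this fixture; it exists so the gene-locus
machinery runs offline end to end.

## Analysis

* **Fiber axis and packing ratio.** The axis is a cubic smoothing spline
  through the core centers (one coordinate at a time against the core
  index); the packing ratio is `11 * NC / Fl` nucleosomes per 11 nm. The
  default spline flexibility (one effective degree of freedom per three
  cores, minimum 4) is a tuned constant chosen so the axis of an ideal
  zigzag runs between the two nucleosome stacks — for a 50-core 26 bp
  zigzag the axis length is ~295 nm where the through-core polyline is
  ~1,139 nm — while curved fibers are followed to within ~2%.
* **Sedimentation coefficient.** The Kirkwood-type form
  `S = ((S1-S0) ρ + S0) (1 + R1/NC Σ_{i≠j} 1/R_ij)` with S0 = 11.1 S,
  S1 = 12 S, R1 = 5.5 nm. The double sum runs over ordered pairs i ≠ j
  (each unordered pair contributes twice), the convention under which the
  two-nucleosome case gives 2/R12 — the form of the legacy literature.
* **Radius of gyration** of the core centers about their centroid.
* **Contact maps.** Two nucleosomes are in contact in a frame when any
  element of one (core, linker beads, tails, LH) is within 2 nm of any
  element of the other, measured surface-to-surface (center distance minus
  both excluded-volume radii; the "any element closer than 2 nm" criterion
  reads as a gap). Per-frame contacts are binary and accumulate over
  frames; frequencies are counts over frame count, and raw counts are kept
  alongside. Ensemble maps are elementwise sums of per-trajectory maps —
  the population-level view in which microdomains appear that individual
  trajectories do not show. Linker beads belong half to the upstream and
  half to the downstream nucleosome (ties upstream); bp-resolution maps bin
  elements by genomic midpoint.
* **Contact decay.** `I(k)` sums the interaction mass at offset
  `|i-j| = k` and is normalized by the total off-diagonal mass, so the
  profile is a probability distribution over k. (The alternative — one
  normalizing constant per row — does not yield a distribution and makes
  profiles of different systems incommensurable.)
* **Microdomains.** DBSCAN on the distance matrix `d = 1/frequency`
  (minpoints 5; search radius 3 for 62 bp fibers, 2 for 44 bp and
  life-like, 1.4 for 26 bp). Zero-frequency entries are capped at 10× the
  largest finite distance: DBSCAN needs finite entries and the cap exceeds
  any plausible radius. The implementation is the standard queue-based
  region growing; the test suite checks it against an independent naive
  reference on random instances.
* **Promoter geometry.** Alpha-shape volume of selected core centers
  (x, y, z) and alpha-shape area of their (x, y) projection, alpha = 100 —
  a loose envelope. The area uses the 2D projection rather than the 3D
  surface because the published procedure feeds (x, y) vertex lists for
  area and (x, y, z) for volume. The alpha complex is computed by brute
  force over vertex subsets with an empty-circumsphere test — exact and
  fast for the ≤ 10-vertex promoter sets this is used for (cost grows as
  n choose 4, so this is not a general-purpose alpha-shape engine); a
  deterministic micro-jitter (10⁻⁷ of the extent) breaks cospherical
  degeneracies.
* **Effective TF concentration** — the fraction of bindable beads actually
  engaged, per replica and ensemble-averaged — separates nominal marks from
  realized bridging (rigid LH-compacted fibers engage far fewer).
* **Convergence** is monitored per frame by total energy, end-to-end
  distance, sedimentation coefficient, and the mean nucleosome triplet
  angle.

## Scale of the bundled checks

The published study conditions (50-nucleosome fibers, 50 million steps, 10
replicas; a 129-nucleosome gene locus, 70 million steps, 20 replicas) are
the package defaults (`replicaPlan()` defaults to saving every 100,000
steps, and ensemble assembly takes the final 10 million steps of each
replica, giving 1,000- or 2,000-structure ensembles). The test suite
exercises the same machinery at desk scale as its own design choice:
25-nucleosome fibers, 4 replicas × 500,000 steps, frames every 25,000
steps, with directional rather than quantitative assertions — TF-region
contact enrichment above separation-matched background, sedimentation
increasing from 0% to 25% TF, and LH suppressing restraint engagement on
short-linker fibers. Quantitative reproduction of published ensemble tables
would require the fully calibrated legacy force field and orders of
magnitude more sampling, and is explicitly out of scope.

What the scaled-down runs do show is the mechanism: bridging restraints
reshape the contact map where and only where binding regions are placed,
and their effect is modulated by linker length and LH exactly in the
directions the mesoscale physics predicts. What they do not show is
convergence of absolute observables — at 500,000 steps a 25-nucleosome
fiber is still exploring, and ensemble values carry replicate-level spread.

## Known limitations

* The TF is purely a distance restraint: no explicit protein geometry, no
  rotational alignment of the bound complex, no sequence readout (E-box
  positions enter only through the bindable marks).
* Charges are effective and uniform per species; the DiSCO-style optimized
  core charge distribution of the legacy force field is replaced by a
  configurable ring placement.
* The twist registry does not feed back into bending geometry during
  sampling; twist offsets act through initial structures.
* Tail bond lengths are sampled only through regrowth (which preserves
  them), so tail stretching contributes a static reference energy; tail
  conformational entropy enters through angles and nonbonded terms.
* One restraint per bead means TF concentration saturates at 50% engaged
  beads when every mark pairs up.
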