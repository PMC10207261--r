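---
title: "Validating predicted GPCR structures by trajectory analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating predicted GPCR structures by trajectory analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orstab)
```

## The problem

Machine-learning structure predictors return a single conformation per
protein. For G-protein coupled receptors — and olfactory receptors (ORs) in
particular, which have weak sequence-motif conservation and few close
homologues in structural training sets — that single answer may correspond to
the wrong functional state, or to no physically stable state at all. The
practical remedy is to *test* each candidate model by molecular dynamics:
simulate it, and ask whether the seven-transmembrane (7TM) helical bundle
holds together.

`orstab` implements the analysis side of that protocol as reusable,
ground-truth-testable components:

* **Model comparison** — mutual backbone RMSD between candidate models,
  projected to the plane by classical multidimensional scaling (MDS).
* **Stability descriptors** — heavy-atom RMSD against the starting model,
  TM6–TM7 spacing from fitted helix axes, a configurable activation index
  (linear functional of interhelical Cα distances), and sodium-site
  occupancy at the conserved acidic pocket (Ballesteros–Weinstein 2.50 and
  3.39).
* **Water permeation** — complete intracellular↔extracellular passages of
  individual waters through the receptor interior, under periodic boundary
  conditions.
* **Conformational clustering** — gromos clustering of the concatenated
  ensemble on a mutual RMSD matrix (TM heavy atoms only).
* **Interface contacts and conservation** — TM6–TM7 residue contact maps,
  interface diffs between models, and D/E conservation counting at
  BW-anchored alignment columns.
* **A synthetic trajectory generator** that plants every one of those
  signals with known ground truth.

The package is organised as an analysis workflow: the numbered scripts under
`analysis/` narrate the study end to end, and every computation they perform
lives in exported, unit-tested functions.

## Why synthetic ground truth

Real MD trajectories of a membrane receptor cannot be regenerated at desk
scale, and published trajectory archives are multi-gigabyte downloads. More
importantly, a real trajectory has no *known answer*: one cannot assert that
a permeation detector found "exactly the right" events. The generator
(`make_bundle()`, `make_trajectory()`) therefore builds an idealized 7-helix
bundle in a periodic box and scripts the phenomena the analyses must
recover:

* **Bundle geometry.** Poly-alanine helices (backbone N, CA, C, O plus CB)
  with standard α-helix geometry — 1.5 Å rise and 100° twist per residue —
  placed on a 10 Å circle, axes vertical, alternating direction, joined by
  short loops. The box is 100 × 100 × 120 Å (a typical GPCR/membrane box),
  coordinates centred on the origin so the membrane midplane is z = 0. The
  residues at BW 2.50 and 3.39 are built as Asp and Glu with explicit
  carboxylate-oxygen pseudo-atoms, because those two acidic side chains form
  the class A sodium pocket the ion analyses target.
* **Splaying.** The TM6–TM7 axis distance follows a linear schedule
  (default 8 → 14 Å), realized as rigid radial displacement of both helices.
  8 Å sits in the closed 7–9 Å regime, 14 Å in the open 13–15 Å regime of a
  disrupted interface.
* **Permeation.** Scripted waters follow continuous z-paths through the
  bundle cylinder (complete crossings), or bounce back, or cross *around*
  the protein through bulk, or keep drifting after a crossing until they
  wrap through the periodic z boundary. Only complete through-the-cylinder
  crossings are true events.
* **Ion binding.** A sodium toggles between a bulk parking position and the
  midpoint of the 2.50 carboxylate oxygens on a frame schedule.
* **Noise.** Isotropic Gaussian coordinate noise (default 0.1 Å in the
  study scripts; 0 where a test asserts exact recovery). One seeded RNG
  stream makes every output reproducible byte for byte.

What the generator does **not** emulate: thermal physics (no force field, no
Boltzmann ensemble), lipid molecules (the membrane is a geometric slab),
side chains beyond CB, and gradual unfolding (helices stay internally
rigid). Passing tests therefore demonstrate that the *analyses* are correct
and sharp on planted signals — not that any particular real receptor is
stable. On real trajectories the same code paths run unchanged; only the
interpretation thresholds matter there.

## Numerical choices

**Superposition.** Kabsch, SVD-based, with the sign of the smallest singular
value flipped when the cross-covariance determinant is negative (proper
rotations only, no quaternion path). Collinear point sets are rejected as
ill-conditioned. Pairwise matrices use the trace identity
`rmsd² = (|A|² + |B|² − 2·Σσᵢ)/n`, which halves the work per pair; it loses
half the working precision to cancellation, so identical frames read as
~1e-7 rather than 1e-16 — irrelevant at chemical scales.

**Mutual RMSD.** Computed pairwise with independent fits (no global
reference), O(n²) in the frame count; frame striding (default every 5th
frame in the study scripts) keeps ensembles at a few hundred items. Model
comparison defaults to whole-chain backbone (N, CA, C, O); clustering uses
TM-only heavy atoms, loops excluded — loops are the least reliable part of
both predictions and simulations. Both selections are configurable.

**Classical MDS.** Torgerson scaling (double-centred squared distances,
eigendecomposition) — deterministic, no random initialisation, delegated to
`stats::cmdscale`. Negative eigenvalues (RMSD matrices need not be
Euclidean) are clamped to zero with a warning. The sign ambiguity is
canonicalised by making the first model's coordinate non-negative on every
axis, so repeated runs plot identically. Stress is reported as
`sqrt(Σ(d_emb − d)² / Σd²)`.

**Helix spacing.** `axis_midplane` mode fits each helix's axis per frame
(principal component of its Cα set, oriented +z) and measures the
axis-to-axis distance at the membrane midplane. This is the natural readout
of TM6–TM7 splaying, which is a rigid-body opening at the membrane level;
`ca_com` mode (distance between cytoplasmic-half Cα centroids) is provided
as a cross-check. Note that a principal-component axis through a *discrete*
helix converges to the true axis only as the helix lengthens (the Cα phase
pattern couples weakly to the rise); for 20–25-residue TM helices the
residual tilt is a few hundredths of an Å at the midplane — well below the
0.5 Å recovery tolerance used throughout.

**Permeation geometry.** Space is split by two z-planes (the membrane slab,
default ±20 Å about the slab centre) and a cylinder (default radius 12 Å
around the per-frame TM Cα centroid): IC below, EC above, TM inside the
cylinder, BULK around it. A passage counts only if it runs
compartment → TM → opposite compartment without touching BULK — "through the
receptor", not around it. Compartments are assigned on **box-folded** z
(minimum image about the slab centre) rather than cumulative unwrapped z:
with periodic boundaries the IC and EC reservoirs are one connected body of
water, and a particle crossing the periodic z-boundary moves between them
*without* passing the membrane. Folding makes that move a TM-free
IC/EC transition (correctly ignored), keeps detection exactly time-reversal
symmetric (reversing the trajectory swaps the two direction counts), and is
invariant under frame-rate refinement. A cumulative-unwrapping variant was
rejected because absolute thresholds on an unwrapped coordinate misclassify
compartments once a particle drifts beyond one box period, which breaks the
time-reversal property. `unwrap_z()` is still exported for path inspection.

**gromos clustering.** The standard iteration: the unassigned item with the
most unassigned neighbours within the cutoff (RMSD ≤ cutoff) becomes a
centroid; it and its neighbours form a cluster and are removed. Ties in
neighbour count break to the lowest item index; final ids are 1-based,
ordered by decreasing population (ties by extraction order). The 2.5 Å
default cutoff is the conventional choice for heavy-atom TM clustering. The
implementation is verified against an independent brute-force
re-implementation on hundreds of random matrices.

**Ion site.** A frame is occupied when any tracked sodium is within the
contact cutoff (default 3.0 Å, a typical Na⁺–carboxylate coordination
distance) of any carboxylate oxygen at BW 2.50/3.39, using minimum-image
distances; the protein is assumed whole (not re-wrapped). Occupancy is the
occupied-frame fraction; first binding time is the first occupied frame's
time stamp.

**Activation index.** Implemented as a configurable linear functional —
`intercept + Σ coefᵢ · d(Cαᵢ₁, Cαᵢ₂)` over BW-labelled residue pairs. The
published coefficient calibrations belong to their sources and are supplied
by the user as data (the `analysis/03` script demonstrates the mechanics
with a two-term example). By convention, values below a user-chosen
threshold indicate inactive-like conformations.

**Verdict rule.** The qualitative classifications of a stability study are
operationalized as an explicit rule: `fold_broken` if the maximal TM6–TM7
spacing reaches the opening threshold (default 12 Å — midway between the
closed 7–9 Å and open 13–15 Å regimes); otherwise `water_leak` if at least
one complete permeation occurred; otherwise `stable`. The thresholds are
recorded in every report, and the verdict is a pure function of the recorded
metrics, so any report can be re-derived from its own numbers.

## Design decisions that were genuinely open

* **Backbone definition.** "Backbone RMSD" can mean N,CA,C,O or Cα-only;
  both are supported, N,CA,C,O is the default.
* **BW maps are data, not inference.** The residue → BW table is supplied as
  a two-column TSV. Inferring BW numbering from sequence motifs is unsafe
  for ORs precisely because their motif conservation is weak — the package
  never attempts it.
* **Boxes are orthorhombic only.** Triclinic boxes are rejected with a clear
  error rather than silently mishandled.
* **Planted model sets.** Candidate-model variants displace the base
  structure along random smooth fields orthogonalized against rigid motions
  and against each other, with coefficients taken from planted 2D
  coordinates. Pairwise fitted RMSDs then equal the planted planar distances
  up to second-order rotation effects (≲1e-2 relative for Å-scale
  displacements on a 20 Å structure), which makes the model-comparison and
  MDS stages testable against exact expected values.
* **Contact criterion.** Minimum heavy-atom distance ≤ 4.5 Å by default
  (web-server contact definitions vary and are rarely printed); the cutoff
  is recorded in every contact map, and maps are provably monotone in it.
* **Gaps in alignments** count as "not allowed" in conservation fractions.

## Study dimensions used by the scripts and tests

The mini-study runs 6 models × 3 replicas × 60 frames (1 ns/frame), strides
every 5th frame into a 216-frame ensemble for clustering, and uses 100-frame
trajectories for the single-phenomenon recoveries (splay, ion schedule,
permeation). These sizes keep the full workflow in the low minutes on one
CPU while leaving every planted contrast unambiguous: scripted scenario
groups differ by ~4 Å planted model RMSD against a 2.5 Å cluster cutoff and
0.1 Å coordinate noise.

## Known limitations

* Atom correspondence between structures is positional; there is no
  sequence-alignment-based matching of different proteins.
* The generator's helices are internally rigid — analyses are validated for
  rigid-body rearrangements plus noise, not for melting helices.
* Permeation tracking follows water oxygens only and assumes waters are
  wrapped consistently with the recorded box.
* `ca_com` spacing mode identifies the cytoplasmic half by mean z, which
  assumes a roughly membrane-normal helix.
* Classical MDS is exact only for Euclidean inputs; for strongly
  non-Euclidean RMSD matrices the reported stress is the honest summary of
  the distortion.
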