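---
title: "Physics-informed backmapping of coarse-grained poly(lactic acid): models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Physics-informed backmapping of coarse-grained poly(lactic acid)}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plabackmap)
```

## The problem

Coarse-grained (CG) simulations of polymer melts replace groups of atoms by
beads — here one bead per lactic-acid monomer, placed at the monomer's
center of mass.  The forward map (atoms to beads) is a deterministic linear
operator; the inverse problem, *backmapping*, must produce one plausible
all-atom configuration out of the many consistent with a given bead
configuration, and for poly(lactic acid) (PLA) it must additionally respect
stereochemistry: every monomer carries a chiral alpha carbon, so PLLA, PDLA
and their copolymers have identical constitutions but different
three-dimensional structures.

`plabackmap` implements a neural backmapping pipeline for linear PLA
chains: a bond-vector representation of the atomistic structure conditioned
on the CG beads, a one-dimensional U-net trained with a composite geometric
loss, a deterministic decoder back to Cartesian coordinates, and a
stereochemistry checker/corrector, together with the structural statistics
used to validate the output (dihedral distributions, radial distribution
functions, internal distances, radius of gyration, density).

## Chemical model

An interior monomer `-O-CH(CH3)-C(=O)-` has nine atoms (ester oxygen O1,
alpha carbon C2 with hydrogen H5 and methyl group C4/H6-H8, carbonyl carbon
C3 with oxygen O2); consecutive monomers are linked C3(i)-O1(i+1).  The
chain ends are capped with a hydroxyl hydrogen on the first monomer's O1
and a hydroxyl O3-HO3 on the last monomer's C3, so a chain of *n* monomers
has *9n + 3* atoms — 903 for a 100-mer, and 70 such chains carry 63,210
atoms and 7000 beads.  The cap assignment is inferred from those printed
totals together with the fact that the chain ends are the molecule's only
hydroxyl donors; the individual cap atoms are not tabulated anywhere, which
is why the templates document this as a modeling choice.

One bookkeeping discrepancy is worth noting: the tabulated CG-particle
count for the 30-mer systems (2700) is inconsistent with one bead per
monomer (70 × 30 = 2100).  The package follows the mapping definition, so
`build_system(70, rep("L", 30))` yields 2100 beads.

## Representation and codec

Every atom contributes one row to the network tensors, in a fixed
per-monomer traversal order (O1 → C2 → H5 → C4 → H6,H7,H8 → C3 → O2, caps
at their parents).  The monomer root row carries the *anchor vector* — the
root's offset from the monomer's center of mass — and every other row the
*bond vector* from its traversal parent.  Both are divided by a fixed
rescale factor (0.3 nm, a generous bound on any bond or anchor vector) so
targets fall strictly inside the tanh output range `[-1, 1]`.  Rows are
zero-padded to the smallest power of two that holds a full chain (1024 for
the 100-monomer capacity), and a validity mask excludes padding from every
loss term.

The input features per row are the monomer's bead displacement from the
previous bead (zero for the first monomer; scale 1.5 nm) plus a one-hot
monomer-type code.  Chain-end monomers always get their own types;
interiors share one type per training context, giving `k = 3` slots for a
homopolymer training set, `k = 4` for a copolymer set (L and D interiors
distinct), and `k = 6` when homopolymer and copolymer data are combined
(context-distinct interiors plus shared ends).  The exact content of the
three non-categorical input columns is an implementation decision; the
bead-displacement feature was chosen because it is translation-invariant
and local, and a bead-minus-centroid variant is retained behind the
`cg_feature` switch of `codec_scales()`.

Decoding rebuilds each monomer from its bond vectors along the traversal
and rigidly translates it so its center of mass coincides exactly with its
bead ("COM anchoring").  This makes reconstruction well-posed whether or
not the anchor-vector penalty is used, makes `decode(encode(x)) == x` exact
to floating point, and guarantees that re-mapping the decoded structure
returns the input beads.  The implied inter-monomer bond C3(i)-O1(i+1) is
never used for placement; it is monitored as a quality metric instead.

## Network

The model is a one-dimensional U-net: five encoder blocks (stride-2
convolution, leaky ReLU, batch normalization; filters 64 → 512), five
decoder blocks (stride-2 transposed convolution, ReLU, dropout 0.5 on the
first), skip connections concatenating each encoder level onto the
matching decoder level, and a final stride-1 transposed convolution with a
tanh onto the three vector components.  Kernel width (4), the final
kernel (3), the leaky-ReLU slope (0.2) and concatenation (rather than
addition) for the skips are implementation choices recorded in every
checkpoint.  The engine — im2col convolutions on BLAS matrix products,
exact adjoint transposed convolutions, hand-derived backward passes, and
Adam — is part of the package and is verified against finite-difference
gradients in the test suite.

## Loss

Training minimizes a weighted sum of five mean penalties, all computed on
unscaled (nm) vectors so the weights are physically comparable: squared
bond-vector deviations, squared bond-length deviations, squared
bending-angle deviations, a periodic dihedral penalty `1 - cos(dphi)`, and
squared anchor-vector deviations.  Angles and dihedrals are functions of
the reconstructed positions, which under COM anchoring are *linear* in the
bond vectors; their gradients are propagated analytically through that
linear map.  The reference weighting penalizes bond vectors and bond
lengths only (`loss_weights(bv = 1, bl = 1)`); the other terms are
available for experimentation.  Whether the angle terms compare raw angles
or trigonometric transforms is not observable near the optimum; the
package uses raw squared differences for bending angles and the periodic
cosine form for dihedrals.

Training follows the reference protocol: mini-batches of 64, Adam at
initial learning rate 0.001, multiplied by 1/8 whenever the validation
loss fails to improve for a patience window (default 20 epochs; the window
and the relative improvement threshold of 1e-4 are not specified anywhere
and are package defaults), floored at 1e-6; data split 80/10/10 by frame;
the best-validation weights are retained.

## Synthetic ensembles

Because the original melt trajectories are not deposited, the package
ships a generator whose ensembles have fully known statistics.  Chains are
grown by the standard internal-coordinate (NeRF) construction: every bond
at its exact configured length, bending angles Gaussian, torsions drawn
from wrapped-Gaussian mixtures per dihedral class, with the backbone
classes mirrored between L and D labels.  The alpha-carbon substituents
are placed at ±120° about the backbone reference torsion with the sign set
by the stereo label, so chirality is correct by construction.  Frames are
independent: chains are re-grown, randomly rotated, and placed uniformly
in a periodic box sized to a melt density of 1100 kg/m³.  Defaults follow
the reference study conditions (70 chains × 100 monomers, frames every
200 ps over 1 μs, i.e. 5000 frames).

Geometric defaults are loosely PLA-like — C-O 0.144/0.134 nm, C-C
0.152-0.153 nm, C-H 0.109 nm, near-tetrahedral angles with 2-2.5° spread,
a trimodal backbone torsion at (-60°, 60°, 180°) with weights
(0.5, 0.3, 0.2) and ~18° mode width, an ester torsion narrowly peaked at
180° — chosen once as plausible for a flexible polyester melt; they are
generator configuration, not a force field.  What the generator does *not*
emulate: excluded volume between chains (an optional soft-core rejection
exists but is off by default), time correlation between frames,
and any energetic coupling between neighbouring torsions.  Tests passing
on these ensembles therefore validate the machinery — representation,
optimization, reconstruction, bookkeeping — not the physics of any real
melt.

## Stereochemistry

The chirality of a monomer is the sign of the signed volume
`det[r_O1 - r_H5, r_C3 - r_H5, r_C4 - r_H5]` at its alpha carbon; the
sign-to-label convention is fixed by the generator's canonical L monomer
(negative = L) and is consistent with CIP rules for the fixed substituent
priority O1 > C3 > C4 > H5 (L = S), which `cip_label()` cross-checks
independently.  Near-planar centers (|det| < 1e-6 nm³) are reported as
undefined rather than guessed.

Correction reflects H5 and the methyl group through the plane spanned by
C2, O1 and C3 — the unique plane that keeps the backbone fixed while
swapping the two off-backbone substituents.  The exact reflection plane
used by the original procedure is not stated; this choice is validated by
its properties (isometry on the reflected atoms, involution, label flip).
Reflection can create close contacts; the pipeline reports a
minimum-distance audit and leaves relaxation to external molecular
dynamics, which is out of scope.  After correction the pipeline rigidly
re-anchors each monomer's center of mass on its bead, since reflection
moves the center of mass slightly and bead consistency is part of the
output contract.

## Analysis choices

Dihedral histograms use 100 bins over (-180°, 180°] by default.  RDFs use
0.01 nm bins, minimum-image distances in orthorhombic boxes, and
ideal-gas normalization at the admissible-pair density; intramolecular and
intermolecular modes restrict pairs to same or different chains.  Internal
distances are computed from unwrapped coordinates.  Uncertainty is
estimated by block averaging with four contiguous blocks.  The atom
selections for RDFs are user-configurable rather than hard-coded, since
the reference selections are identified only in figures.

## Problem sizes used by the shipped checks

The test suite exercises the full pipeline at reduced scale, chosen so the
whole suite runs on a single CPU: topology and codec checks use chains of
1-100 monomers; the end-to-end check trains on a synthetic ensemble of 10
chains × 20 monomers × 500 frames (5000 chain samples, tensor length 256)
with a 16-filter-base U-net for 25 epochs, then verifies that training and
validation losses decrease together to a plateau and compares 25 backmapped
held-out frames against the generator's backbone torsion mixture and
bond-length peaks.  Distributional agreement demands very accurate vector
predictions (sub-0.01 nm per component); a short CPU run does not reach
that accuracy, so the distributional comparison is reported as measured
rather than guaranteed.  The narrower network and shorter schedule relative to the
reference configuration (64 filters, ~1000 epochs on a GPU) are a
deliberate scaled-down study design; the architecture, loss, optimizer
and data flow are identical.

## Known limitations

- Chains must be linear PLA; no rings, branches, or other chemistries.
- The network input length is fixed per checkpoint; longer chains are
  processed as consecutive fragments, which ignores correlations across
  fragment boundaries.
- A deterministic network predicts one configuration per CG input; the
  spread of the predicted torsion distributions comes from the diversity
  of CG inputs, not from sampling noise, and can be narrower than the
  target distribution when training is short.
- No force-field energetics anywhere: outputs are geometric
  reconstructions intended as starting points for external relaxation.
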