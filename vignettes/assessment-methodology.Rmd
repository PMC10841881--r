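---
title: "Assessing predicted protein assemblies: models, metrics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing predicted protein assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capriq)
```

## The assessment problem

Blind prediction rounds for protein complexes judge a predicted ("model")
assembly against the experimentally determined ("target") structure. capriq
implements the full evaluation chain used in that setting: per-interface
quality metrics, a discrete four-category quality label, the continuous
DockQ score, aggregation of multi-interface targets into assessment units
(AUs), and ranking of predictor groups across many targets.

## Quality metrics for one interface

An evaluated interface is a pair of interacting chains in the target. Four
measures are computed per model:

* **fnat** — the fraction of the target's native residue-residue contacts
  recalled by the model. Two residues across the interface are in contact
  when any heavy-atom pair lies below the contact threshold (5 Å default).
  The denominator is always the *target's* contact count, and contacts
  involving residues the model did not resolve count as missed, so
  truncated models cannot inflate their recall.
* **L_rms** — backbone RMSD (N, CA, C, O) of the ligand chain after
  least-squares superposition of the receptor backbones over the residues
  common to model and target; the ligand is *not* refit. The receptor is
  the chain of the pair with more residues (ties broken by chain id) —
  L_rms is asymmetric, so the convention must be fixed and is reported.
* **i_rms** — backbone RMSD over the interface residues after superposing
  those residues themselves. An interface residue has any heavy atom
  within 10 Å of any atom of the partner chain. Interface residues are
  defined *on the target only*; their model counterparts come through the
  residue correspondence. This keeps i_rms comparable across models of the
  same target; recomputing the interface per model would let a badly wrong
  model choose its own, flattering, interface.
* **S_rms** — RMSD over side-chain heavy atoms of the interface residues,
  evaluated under the i_rms backbone fit (again no refit). It is reported
  as a diagnostic only and never enters classification; with no shared
  side-chain atom (an all-glycine interface) it is flagged undefined.

Inter-chain heavy-atom pairs closer than 3 Å are clashes. The
disqualification threshold for "too many clashes" is batch-relative
(count > mean + 2 SD over all models submitted for the target), with a
configurable absolute cap for single-model runs; by default a single model
is never disqualified, since no absolute number is canonical.

All distance work excludes hydrogens, which are stripped at parse time; for
alternate locations only the highest-occupancy conformer is kept (ties by
altloc letter).

### Residue correspondence

Models frequently renumber residues, so model and target residues are
paired by global sequence alignment (BLOSUM62, end-to-end) per mapped chain
pair, not by author numbering. Because model and target share the construct
sequence, only *identical* aligned residues are paired; a chain pair
aligning below 30% identity aborts with a "wrong chain map" error. In batch
mode the common residue set can additionally be intersected across all
submitted models, so every model is measured over identical residues; the
default remains the per-model target∩model set, because a single-model call
cannot know the batch.

### Superposition

The rigid-body fits use the closed-form least-squares rotation (SVD of the
cross-covariance, reflection branch excluded). The implementation is
authored in the package — it is the computational core of both RMSD
definitions — and is cross-checked in the tests against an independent
fitting routine and against dense random-rotation grids.

## Categories and DockQ

Models fall into four categories, best first: High, Medium, Acceptable,
Incorrect. The canonical threshold table is used (this package exposes it
as configuration):

| category | fnat ≥ | and (L_rms ≤ | or i_rms ≤) |
|----------|-------:|-------------:|------------:|
| High | 0.5 | 1.0 | 1.0 |
| Medium | 0.3 | 5.0 | 2.0 |
| Acceptable | 0.1 | 10.0 | 4.0 |

Thresholds are inclusive (≥ for the fnat floor, ≤ for the RMSD ceilings);
the sources this protocol descends from do not state strictness, so the
choice is documented here and verifiable in `capri_category_table()`.
Disqualified models are forced Incorrect.

DockQ condenses the same three metrics into one continuous score:

$$\mathrm{DockQ} = \tfrac{1}{3}\left( f_\mathrm{nat}
  + \frac{1}{1+(L_\mathrm{rms}/d_1)^2}
  + \frac{1}{1+(i_\mathrm{rms}/d_2)^2}\right),
  \quad d_1 = 8.5\,\text{Å},\; d_2 = 1.5\,\text{Å}.$$

The scaling constants are previously optimized values and are not refit
here. There is no strict correspondence between DockQ and the discrete
categories; `dockq_consistency()` flags models where the label and the 0.23
incorrect cutoff disagree, as a diagnostic that never alters labels.

## Assembly evaluation and assessment units

For multi-chain targets every chain pair with at least one native contact
is an interface. Model chains are mapped onto target chains by searching
the stoichiometry-respecting assignments (permutations within
sequence-equivalence classes): exhaustively up to a configurable budget
(720 mappings by default), then by hill-climbing over within-class swaps.
The mapping maximizing summed per-interface quality wins — category
weights first, total DockQ as the tie-break, with remaining ties resolved
by enumeration order so results are deterministic.

Symmetric copies of an interface in a homo-oligomer are grouped: contact
fingerprints (residue ordinals within chains) are compared under chain
relabeling, and interfaces with Jaccard similarity ≥ 0.7 fall into one
group. Published AU layouts for the split and merged targets (the
trimer-of-trimers, the tube + transmembrane assembly, and the
RuvB/RuvA series) ship as explicit YAML configurations rather than being
inferred, and configuration always overrides the automatic grouping.

An AU with K distinct interface groups scores

$$\mathrm{Score}_{AU} = \omega_1 n_{ACC} + \omega_2 n_{MED} + \omega_3 n_{HIGH},
\qquad (\omega_1,\omega_2,\omega_3) = (1,2,3),$$

where the counts are over groups whose best model (within the top-5
submission) reached at least that category. Counting is *exclusive*: each
group counts once, in its best category. Read literally, the defining text
would let one High model increment all three counters; exclusive counting
keeps Score_AU ≤ 3K and matches how the group-level score treats a target.
This was a genuinely open reading and is settled here as a design choice.
The normalized score divides by K so large assemblies do not dominate
group rankings. The AU-level DockQ is the mean over distinct groups of the
per-group best DockQ, replicas contributing through their best copy only.
For the tube assembly's first AU, the tube interfaces and the C-terminal
domain interface remain two evaluated interfaces (K = 2) unless its
configuration says otherwise.

## Group ranking

Per group, the best model among the top-n ranked submissions (n = 5
default; n = 1 for top-1 analyses) represents each AU: highest category,
then higher DockQ, then lower rank number. Three rankings are computed:

* **CAPRI score** — the weighted count above, over AUs; multi-interface
  AUs contribute their normalized AU score.
* **ΣDockQ** — the sum of per-AU best DockQ values. Unlike the CAPRI
  score this includes contributions from sub-cutoff (incorrect) models.
* **ΣZ⁺** — per AU, scores are standardized across groups and negative
  Z-scores truncated to zero before summing. Standardization is per AU
  (matching how per-target Z-based rankings are customarily built);
  groups missing a target enter as 0 before standardization, and a
  zero-variance AU contributes Z = 0 to everyone — there is no
  information to rank on, and this avoids a division by zero. Whether the
  DockQ or the CAPRI contribution is standardized is exposed as an
  option; DockQ is the default. Final ties break lexicographically by
  group id, purely for deterministic output.

## The synthetic complex generator

Toy complexes are built from ideal α-helices (rise 1.5 Å, twist
100°/residue) with deterministic aperiodic sequences over five residue
types and schematic side chains placed radially. Chains are arranged as C2
dimers, hetero dimers, or C3–C6 rings at the smallest clash-free
separation that leaves at least 10 native contacts; the relative helix
phase (and, for rings, an axis tilt) is searched because the helix surface
is bumpy. Everything is deterministic from the specification: the same
spec yields bit-identical coordinates.

Decoys perturb one subunit — rigid translation and rotation about its
centroid, optional Gaussian side-chain jitter, optional C-terminal
truncation. Two handles make them self-validating:

* a pure translation **t** of the ligand with the receptor untouched gives
  L_rms = |t| *exactly*, and
* side-chain jitter of σ per coordinate drives S_rms toward σ√3.

All other expected values come from the module's own brute-force oracle
(dense all-pairs contact enumeration plus an independent fitting routine),
so each decoy carries its own truth. The decoy ladder rejection-samples
perturbations per intended category and rejects samples within 5% of any
category threshold, keeping truth labels stable under floating-point
variation.

What the generator does *not* emulate: real fold geometry, realistic
side-chain rotamers and packing, sequence/structure co-variation,
missing-density patterns of cryo-EM maps, or the error modes of deep
learning predictors. Passing the synthetic suite therefore demonstrates
that the measurement machinery is correct, not that any prediction method
is good; conclusions about real targets require real structures.

## Problem sizes and numerical choices

The shipped tests run the metric/oracle comparison on 200 generated decoys
over two base complexes (chains of 15–30 residues), the superposition
optimality check on 25 random instances against 500-rotation grids,
classification monotonicity on a 20³ metric grid, ladder recovery on 100
oracle-labeled decoys, and the scoring algebra on 1000 random manifests
plus 100 simulated rounds — sizes chosen so the whole suite completes in a
few minutes on one core while leaving each property no room to pass by
accident. Contact searches use a 27-cell spatial grid whose results are
required (by test) to be identical to the dense enumeration. Superposition
declares point sets collinear below a 1e-8 singular-value cut; rotations
carry det = +1 to 1e-8.

## Known limitations

* Chain-mapping search beyond the exhaustive budget is heuristic
  (hill-climbing); a pathological homo-24-mer could in principle settle in
  a local optimum.
* mmCIF support covers the `atom_site` loop (auth_* identifiers), not
  assemblies defined via crystallographic symmetry operators; no structure
  repair or side-chain rebuilding is attempted.
* The batch clash-disqualification rule needs a batch; single-model runs
  disqualify only via the configurable absolute cap.
* BSA values in the packaged target table are transcribed metadata and are
  never recomputed; interface areas play no role in any score here.
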