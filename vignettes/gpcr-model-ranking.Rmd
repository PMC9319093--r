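---
title: "Ranking GPCR structural models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking GPCR structural models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gpcrstars)
```

## The problem

When no experimental structure of a receptor exists, structural models from
homology modelling, threading, and deep-learning predictors must be compared
and a few carried forward into docking and molecular-dynamics work. For a
class A G-protein-coupled receptor (GPCR) in the *inactive* state that
comparison has three distinct axes:

1. **stereochemical / statistical quality** - a dozen established global
   scores (ERRAT, VERIFY 3D, PROVE, Ramachandran statistics, RWplus,
   MolProbity, Rosetta energy, DFIRE, GOAP, OPUS-PSP, a predicted global
   quality score) that disagree in scale, direction and units;
2. **state-defining geometry** - inactive class A receptors close an
   "ionic lock" between R^3.50^ at the cytoplasmic end of TM3 and a TM6
   partner (S^6.33^ in the receptor this package's fixtures describe,
   GPR18), keep the intra-helical R^3.50^-D^3.49^ "aspartate cage" salt
   bridge of the DRY motif, and hold the cytoplasmic TM3-TM6 Calpha
   separation near 10-12 Å (active structures open to ~15-16 Å);
3. **function** - a useful model must rank known active ligands above
   inactive ones when a docking engine scores a mixed library (enrichment,
   summarised by the ROC AUC).

`gpcrstars` implements the aggregation and measurement layer for this
workflow. It does not run any predictor, docking engine or MD code: it
consumes their outputs (score tables, PDB coordinates, pocket-residue
lists) and makes the comparison reproducible.

## The "Stars" aggregation

Each metric is reduced to 0-3 stars using three ordered boundary values
(3-, 2- and 1-star boundaries; failing all three gives 0). Boundaries are
*inclusive* in the direction of their comparator: VERIFY 3D `>= 61` earns
exactly one star at 61.0; MolProbity `<= 1.0` earns three at 1.0.

Two deliberate features of the scheme:

* the Ramachandran **core** and **disallowed** percentages are binned
  separately at weight 0.5 each and then summed, so the Ramachandran
  contribution is half-star granular in [0, 3];
* a missing metric contributes 0 stars rather than excluding the model, so
  models scored by fewer tools remain comparable (they simply cannot reach
  the 36-star ceiling of the 12-metric scheme).

Boundaries can either be loaded from a published range table
(`default_star_spec()`, shipped as a JSON fixture) or derived from a model
population with `derive_thresholds()`, which places them at the quartiles
of the observed values (`stats::quantile()` type 7, the R default - the
original procedure is described only as "quartiles from box plots", which
any of the common quantile definitions satisfies to within one member per
bin). The packaged table is the default because it is the one that is
actually printed; re-derivation is for new model pools.

### The print-scale convention for RWplus and GOAP

Published score workbooks frequently print the RWplus and GOAP potentials
divided by ten relative to the scale of their star boundaries (e.g.
`-7987` against a 3-star boundary of `<= -79,000`). `read_quality_table()`
therefore multiplies these two columns by ten on ingest behind an explicit
flag (`rescale_energies`, default `TRUE`). With that convention six of the
eight fixture models reproduce their published totals exactly:

```{r}
st <- star_table(gpr18_quality_table())
st[c("model", "total")]
```

The `CF-DM` and `PF-DM` rows are **not** reproducible from their printed
raw values under any binning we tried (computed 3.5 and 2.5 against
published totals of 11.5 and 8.5); the discrepancy is documented rather
than papered over, and those two models are excluded from exact-match
tests. Their *secondary*-ranking inputs (which start from the published
totals) do reproduce.

## The secondary (V1/V2/V3) ranking

Three coarse criteria each earn 0-3 stars:

| criterion | 3 | 2 | 1 | 0 |
|---|---|---|---|---|
| V1: star total | >= 27 | >= 20 | >= 13 | < 13 |
| V2: ionic-lock distance | <= 2.5 Å | <= 3.5 Å | <= 4.5 Å | > 4.5 Å |
| V3: enrichment AUC | >= 0.79 | >= 0.77 | >= 0.75 | < 0.75 |

`rank_models()` sorts by the V1+V2+V3 sum in descending order. The source
procedure is silent on ties (its own sums tie four models at 6), so the
package breaks them deterministically: higher preliminary star total
first, then smaller lock distance, then lexicographic model name. The full
ordering is reproducible from the same inputs on any machine.

```{r}
rank_models(gpr18_secondary_table())[c("rank", "model", "v1", "v2", "v3", "sum")]
```

## Generic numbering

All geometry is addressed through Ballesteros-Weinstein generic numbers
(`3.50`, `6.33`, ...), assigned from per-segment anchors: the residue
declared `X.50` fixes the frame and every other residue in the segment
span follows by sequence offset. Loops use GPCRdb-style two-helix labels
(the conserved EL2 cysteine is `45.50`). Helix spans are *not* part of the
published record for GPR18; the packaged anchor fixture
(`gpr18_anchors()`) uses spans chosen once to cover every residue the
literature labels, and is user-overridable through `read_anchors()`. The
EL2 span is deliberately narrow (170-174) so that deeper EL2 residues
(I175, S176, ...) exercise the composite `chain:resno` labelling that the
pocket-fingerprint module uses for un-numbered loop residues. Insertion
codes participate in residue identity but not in offset arithmetic; spans
containing them are rejected.

## Geometry metrics and their conventions

* **Ionic lock** (`ionic_lock()`): the ranking quantity is the minimum
  distance from the serine side-chain oxygen to any arginine guanidinium
  hydrogen; the N-O heavy-atom distance and the N-H...O angle at the
  minimising hydrogen are reported alongside. Models from many pipelines
  carry no hydrogens; rather than invent positions, the measurement then
  degrades to the heavy-atom N-O minimum with an explicit
  `has_hydrogens = FALSE` flag. Hydrogens are recognised by element and a
  1.25 Å covalency radius to NE/NH1/NH2, so naming schemes do not matter.
* **Aspartate cage** (`aspartate_cage()`): minimum over
  {NE, NH1, NH2} x {OD1, OD2}; a companion boolean calls a salt bridge at
  the conventional 4.0 Å heteroatom cutoff, but the raw distance is always
  the primary output.
* **TM3-TM6 distance** (`tm3_tm6_distance()`): the literature defines the
  gauge as the average Calpha distance between residues 3.51-3.55 and
  6.30-6.34 without fixing a pairing. The default mode `"paired"` aligns
  the stretches at their cytoplasmic ends (TM3 and TM6 are antiparallel,
  so 3.51 pairs with 6.34); `"index"` and `"all-pairs"` cover the other
  plausible readings, and the mode used is recorded on the result so the
  ambiguity can never silently change a number.
* **State classification** (`classify_state()`): `inactive` up to 12 Å,
  `active` from 14 Å, `intermediate-ambiguous` between; both bounds are
  arguments.
* **Superposition** (`superpose()`): standard Kabsch SVD solution with the
  reflection correction; degenerate (collinear or < 3 atom) selections are
  rejected rather than silently fitted.

Trajectories are ingested as multi-MODEL PDB files (portable, text-only);
binary trajectory formats are deliberately out of scope, with
`as_trajectory()` as the adapter point for anything that can produce
per-frame structures. Per-frame metric failures become explicit `NA` gaps
in `metric_series()` - never interpolated - while a failure on frame 1 is
treated as "metric inapplicable" and raised.

### Interaction fingerprints

The per-frame protein-ligand fingerprint uses purely geometric criteria,
all exposed as arguments because no published criterion set exists at this
level: hydrogen bond at donor-acceptor heavy-atom distance <= 3.5 Å (plus a
D-H...A angle >= 120° when hydrogens are resolved), hydrophobic contact at
any C-C pair <= 4.0 Å, aromatic proximity at ring-centroid distance
<= 5.5 Å using the standard Phe/Tyr/Trp/His ring templates (ligand rings
are supplied by the caller or the residue is skipped with a warning).
These defaults are common practice but are *defaults*, not claims;
`persistence()` then reports the fraction of frames each contact survives.

## Enrichment

`label_by_potency()` applies a strict `IC50 < 10 uM` activity cutoff (a
ligand at exactly 10 uM is inactive). `roc_auc()` sweeps score thresholds
with tied scores collapsed to single ROC points, so the trapezoidal area
equals the Mann-Whitney U statistic with half credit for ties - an
identity the test suite verifies against exhaustive pair counting. Score
direction is explicit (`"lower"` for Vina-style more-negative-better,
`"higher"` for DockThor-style affinity scores) because a silent sign
convention is the classic way to report 1 - AUC.

## What the synthetic generators emulate

The synthetic module exists so that every stage can be tested with known
ground truth, with the recovery loop (generate with known parameters ->
measure -> compare) as the central test pattern:

* `gen_quality_table()` samples metric values *inside* chosen star bins,
  so the expected total is known by construction.
* `build_bundle()` produces ideal alpha-helical Calpha traces (1.5 Å rise,
  100°/residue twist, 2.3 Å helix radius, axes on an 11.5 Å circle; TM
  helices alternate direction, so TM3 and TM6 are antiparallel). TM6 is
  translated rigidly until the paired cytoplasmic distance equals the
  `tm3_tm6` target; lock and cage pseudo side-chain atoms are then placed
  by constrained collinear/perpendicular geometry so the measured
  `lock` and `cage` values equal their targets essentially exactly
  (tests require 0.05 Å). Defaults (11 Å, 2.0 Å, 2.8 Å) describe an
  inactive-state receptor. An *active* TM3-TM6 target combined with a
  short lock target is rejected as infeasible - the arginine cannot reach -
  which mirrors the physics: the lock breaks when the helices separate.
  Requesting `lock = NA` instead places a canonically extended side chain
  and lets the distance fall where geometry puts it.
* `gen_trajectory()` rebuilds the bundle per frame with linearly
  interpolated targets (drift) and adds iid Gaussian noise per coordinate;
  with noise sd σ on both the reference and the moving frame, the expected
  superposed RMSD is ≈ σ√6, which the tests check at 10%.
* `gen_docking_scores()` draws two Gaussian score classes with shared sd,
  for which the population AUC is exactly Φ(|Δμ|/(σ√2)). Defaults
  (26 active / 98 inactive, class means -9.2 / -8.0, sd 1) give an
  analytic AUC ≈ 0.802, the regime typical of a focused screening library.

What the generators do **not** emulate: real side-chain rotamers and
packing, loops with secondary structure, membranes, force-field
energetics, correlated MD fluctuations, or docking-score distributions
with heavy tails. Passing the recovery tests therefore demonstrates that
the *measurement and aggregation* code is correct, not that any particular
modelling pipeline produces good receptors.

## Problem sizes and numerical choices

The shipped tests run the full suite in a few seconds: bundles of ~230
atoms, trajectories of 3-20 frames, 100 random score tables for the
AUC/pair-count identity, and 1000 ligands per class for the analytic-AUC
convergence check (compared within three standard errors using the
Hanley-McNeil variance approximation). TM6 placement iterates rigid shifts
to |d - target| < 1e-9 and refuses specs that fail to converge within
0.05 Å. Alternate locations resolve to the highest occupancy with ties to
`'A'`. All coordinates and distances are in Ångström; residue numbering is
1-based author numbering exactly as in the PDB records.

## Known limitations

* The star scheme inherits the arbitrariness of its boundaries; totals
  are ordinal, not interval - a 22 is not "twice as good" as an 11.
* Two of the eight fixture models carry published totals that their
  published raw values cannot reproduce (see above); their totals are used
  only where the published value itself is the input.
* The ionic-lock measurement depends on hydrogen presence; mixing
  hydrogenated and hydrogen-free models mixes H...O and N-O distances, so
  compare the `has_hydrogens` flags before comparing distances.
* Pocket consensus requires an explicit `min_models`; no default is
  offered because the right cut depends on how many models were fed in.
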