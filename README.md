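# gpcrstars

Star-based quality ranking and activation-state geometry for GPCR
structural models.

## What this is for

Structural biologists and CADD practitioners working on receptors without
an experimental structure routinely generate many candidate models
(homology modelling, threading, trRosetta/RoseTTAFold/AlphaFold-family
predictors) and must pick the few worth docking and simulating. The
comparison cuts across incommensurable evidence: a dozen global
quality scores with different scales and directions, inactive-state
hallmark geometry, and the model's ability to enrich known actives in a
virtual screen. `gpcrstars` implements that comparison as a reproducible
pipeline:

* **"Stars" aggregation** — each quality metric *m* with value *x_m* gets
  `s_m ∈ {0,1,2,3}` stars from three ordered, inclusive boundaries
  (published table or quartile-derived via `derive_thresholds()`), and a
  model's total is the weighted sum `S = Σ_m w_m · s_m` with `w = 0.5` for
  the two Ramachandran percentages and 1 otherwise (`S ∈ [0, 36]`, half-star
  grid). Missing metrics contribute 0.
* **Secondary V1/V2/V3 ranking** — V1 bins `S` (≥27/≥20/≥13), V2 the
  R^3.50–S^6.33 ionic-lock distance (≤2.5/≤3.5/≤4.5 Å), V3 the enrichment
  AUC (≥0.79/≥0.77/≥0.75); models are ranked by `V1+V2+V3` descending
  with a documented deterministic tie-break.
* **Activation-state geometry** — ionic lock (nearest donor-H to acceptor-O,
  with heavy-atom fallback), D^3.49–R^3.50 aspartate-cage distance, and the
  cytoplasmic TM3–TM6 Cα distance (3.51–3.55 vs 6.30–6.34; ~10–12 Å
  inactive, ~15–16 Å active), addressed by Ballesteros–Weinstein generic
  numbers built from per-segment anchors.
* **Trajectory analysis** — per-frame metric series, Kabsch-superposed RMSD
  vs frame 1, geometric protein–ligand interaction fingerprints and their
  per-contact persistence.
* **Enrichment** — strict IC50 < 10 μM activity labelling and a tie-aware
  ROC whose trapezoidal area equals the Mann–Whitney AUC.
* **Pocket fingerprints** — binary model × residue matrices from predicted
  binding-site lists, consensus residues, Jaccard similarities.
* **Synthetic data** — generators for quality tables with known totals,
  ideal 7-TM bundles with exact-target motif geometry, noisy trajectories,
  and two-class docking scores with analytic AUC `Φ(|Δμ|/(σ√2))`, so every
  stage is testable without downloads.

## Worked example

Rank the eight packaged receptor models (raw metric values ship as a
fixture; RWplus/GOAP arrive on the divided-by-ten print scale and are
rescaled on ingest):

```r
library(gpcrstars)

st <- star_table(gpr18_quality_table())
st[c("model", "total")]
#>    model total
#> 1  AF-DM  19.0
#> 2  CF-DM   3.5
#> 3  PF-DM   2.5
#> 4   TR_1  32.0
#> 5  TTA_5  16.0
#> 6  CIT_1  22.0
#> 7   IT_1  11.5
#> 8 PY3_10   4.0

rank_models(gpr18_secondary_table())[c("rank", "model", "v1", "v2", "v3", "sum")]
#>   rank  model v1 v2 v3 sum
#> 1    1  CIT_1  2  3  3   8
#> 2    2   TR_1  3  2  1   6
#> 3    3  TTA_5  1  2  3   6
#> 4    4   IT_1  0  3  3   6
#> 5    5 PY3_10  0  3  3   6
#> 6    6  CF-DM  0  2  3   5
#> 7    7  PF-DM  0  2  2   4
#> 8    8  AF-DM  1  1  1   3
```

CIT_1 tops the ranking at 8 of 9 possible secondary stars: a decent star
total (22 → V1 = 2), a closed ionic lock (2.09 Å → V2 = 3) and strong
enrichment (AUC 0.811 → V3 = 3). TR_1 has the best raw quality total (32)
but weak enrichment drags it into the four-way tie at 6.

Geometry on a synthetic inactive-state bundle:

```r
b <- build_bundle(bundle_spec(tm3_tm6 = 11, lock = 2.09, cage = 2.8))
tm3_tm6(b)                    #> 11
ionic_lock(b)$h_distance      #> 2.09
classify_state(tm3_tm6(b))    #> "inactive"
```

## Layout

```
R/                 implementation (numbering, quality, secondary, structure,
                   geometry, trajectory, enrichment, pocket, synthetic)
inst/extdata/      plain-text fixtures (anchor map, star ranges, score
                   tables, synthetic pocket predictions)
tests/testthat/    unit, property and acceptance tests
vignettes/         methods vignette: model, conventions, design decisions
scripts/           acceptance script
```
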