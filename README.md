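# tilePheno

Tile-based multiplex IHC phenotyping of pancreatic ductal adenocarcinoma
(PDAC).

PDAC tumors mix cell populations of the two major transcriptomic subtypes
— classical (better prognosis) and basal-like — plus an intermediate
state, within a single lesion. `tilePheno` quantifies that intratumor
heterogeneity from serial-section immunohistochemistry: co-registered
binary positive-pixel masks for a seven-marker subtype panel (GATA6,
CLDN18, TFF1, MUC16, S100A2, KRT17, PanBS) plus pan-cytokeratin (PANCK)
are cut into 200-µm square tiles over a pathologist's tumor annotation,
and each tile *i* is summarized by its positive-pixel proportions
*p*<sub>im</sub> ∈ [0, 1] per marker *m*.

The analysis chain is:

1. **Registration** — per physical slide, a rigid transform (dx, dy, θ)
   maximizing the Dice overlap with the PANCK reference (grid search over
   rotations + FFT cross-correlation over translations, refined to
   0.1 px / 0.1°).
2. **Tiling & filtering** — grid tiles over the annotation; keep
   non-truncated tiles, then tumor tiles with PANCK proportion strictly
   > 10%.
3. **Clustering** — features log₂(*p* + ε) over the seven subtype markers,
   PCA components with > 5% explained variance, k-means with k selected by
   the mean silhouette width; clusters named by marker-dominance rules into
   Classical, Intermediate (KRT17⁺), Basal.MUC16 and Basal.S100A2.
4. **Composition** — per-tumor phenotype proportions with strict presence
   (> 1%) and predominance (> 50%) calls, and a basal-present flag on the
   summed basal proportion.
5. **Statistics** — phenotype co-occurrence (two-sided Fisher exact per
   tumor pair, BH-adjusted), predominant-phenotype shifts across slides,
   Kaplan–Meier / log-rank and multivariate Cox (Breslow ties) for overall
   survival by basal presence, with the standard clinicopathological
   covariates.
6. **Marker triage** — signature correlation / Mann–Whitney AUC screening,
   the three TMA specificity rules, and the H-score-vs-RNA concordance
   keep/drop rule (H-score = intensity 0–3 × percent positive cells,
   range 0–300).

Because no public cohort accompanies the method, a synthetic-data module
generates every input — tile tables, slide stacks, survival cohorts, TMA
tables — with planted ground truth, so the whole chain is validated by
recovery of known quantities.

## Worked example

```r
library(tilePheno)
cfg <- analysisConfig(seed = 1)   # all published thresholds as defaults
res <- runPipeline("pdac_run", cfg, nTumors = 60, nTilesPerTumor = 60)
```

which prints:

```
[simulate] slide stack, cohort (n = 60), 60 tiles/tumor
[register] 5 slides aligned to PANCK
tiles: 25 total -> 9 non-truncated -> 9 tumor (PANCK > 0.1)
[tile] 25 -> 9 tiles after the two-step filter
[cluster] k = 4 selected by silhouette
[phenotype] pooled basal/classical/intermediate = 21.6% / 25.7% / 52.7%
[stats] log-rank p = 0.0654; basal HR = 1.59
```

Reading the output: the five simulated slides (with planted
misalignments) are re-registered to the PANCK frame; the demonstration
annotation yields 25 tiles of which 9 survive the two-step filter; on the
cohort's 3,600 tiles the silhouette method selects the four canonical
tile phenotypes; pooling all tiles gives the basal/classical/intermediate
mix; and the survival layer estimates the basal-presence hazard ratio on
the simulated cohort (planted HR = 2; at n = 60 the estimate 1.59 with CI
0.85–2.99 is within sampling noise — larger cohorts tighten it, e.g.
`generateCohort(500, ...)` recovers ≈ 1.9–2.3). Outputs (tile tables,
labels, compositions, co-occurrence, KM curves, Cox table, transforms,
model JSON, manifest) are written under `pdac_run/` and are bit-identical
across runs with the same seed.

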