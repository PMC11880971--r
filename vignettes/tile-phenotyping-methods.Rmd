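---
title: "Tile-based IHC phenotyping of PDAC: models and methods"
author: "tilePheno maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tile-based IHC phenotyping of PDAC: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tilePheno)
```

# The problem

Pancreatic ductal adenocarcinoma (PDAC) carries two major transcriptomic
subtypes — classical (better prognosis) and basal-like — but individual
tumors are rarely pure: classical, basal and intermediate cell populations
co-exist within one lesion, and even a minor basal contingent worsens
prognosis. Bulk RNA cannot resolve this spatial mixture. `tilePheno`
implements an immunohistochemistry (IHC) route: serial sections are stained
for a seven-marker subtype panel (GATA6, CLDN18, TFF1 — classical; MUC16,
S100A2, KRT17, PanBS — basal spectrum; PanBS is a single channel standing
for a KRT5/KRT14/p63 cocktail) plus pan-cytokeratin (PANCK) as the
epithelial gate, the annotated tumor area is cut into 200-µm square tiles,
and each tile is summarized by the proportion of positively stained pixels
per marker. Unsupervised clustering of these tile profiles yields a small
set of tile phenotypes whose per-tumor mixture quantifies intratumor
heterogeneity.

# Pipeline and models

## Registration

Serial sections are not pixel-aligned after digitization. The package
models the residual misalignment per physical slide as a 2-D rigid
transform (dx, dy in pixels; θ in degrees, counter-clockwise), mapping
moving coordinates into the reference (PANCK) frame. Estimation maximizes
the Dice overlap of foreground masks: rotations are scanned on a grid
(default ±5° in 0.5° steps) and, for each rotation, the best integer
translation is obtained in one FFT cross-correlation (the Dice numerator
for all shifts at once, default bound ±50 px), followed by coordinate-wise
hill climbing down to 0.1 px / 0.1°. Channels stained on the same physical
slide share one transform, estimated from the union of their masks — a
duplex stain moves as a unit.

Two caveats are deliberate: the model is rigid only (tissue deformation
between sections is out of scope — the synthetic data are rigid by
construction, and a rigid stand-in keeps the stage exactly testable), and
binary masks make the Dice surface piecewise constant, so the sub-pixel
refinement is only as informative as the mask's spatial detail. On blocky,
nearly symmetric masks the rotation is weakly identified; masks with
off-centre structure pin it to the grid step.

## Tiling and quantification

An axis-aligned grid of square tiles (side = round(tileSizeUm / mpp) px;
200 µm default) is anchored at the annotation bounding-box origin — the
simplest convention that is exactly reproducible; no overlap, no offset
sweep. Every tile intersecting the annotation is emitted with its
`inside_fraction`; "non-truncated" means `inside_fraction = 1` by default
(the threshold is configurable, since the original filtering rule is
stated only as "based on size"). Pixel boxes are 0-based and half-open.

Per tile and channel, the proportion is positive pixels within the
tile–annotation intersection divided by the intersection area (not the
full tile area), so boundary tiles remain unbiased if a relaxed truncation
threshold retains them. The two-step filter then keeps (1) non-truncated
tiles, (2) tiles with PANCK proportion strictly greater than 10% — the
strict inequality mirrors the phrase "more than 10%", and the same
strictness is applied to all presence calls below. Filtering is
idempotent and order-preserving.

H-scores (intensity class 0–3 × percent positive cells 0–100, range
0–300) are computed for TMA-based marker triage and concordance checks.

## Clustering

Tile features are `log2(proportion + ε)` over the seven subtype markers
(PANCK is a gate, not a signal). ε defaults to 1e-3: proportions of 0 are
legitimate and frequent, and 1e-3 sits an order of magnitude below the 1%
presence scale so it compresses nothing that matters; it is exposed in the
configuration because the original log transform's pseudo-count is
unstated. Columns are centred but not variance-scaled before PCA — the log
already stabilizes scale, and scaling would inflate near-empty markers;
this too is configurable. Components with explained-variance ratio
strictly above 5% are retained; each component's sign is fixed (largest
loading positive) so scores are reproducible across platforms.

k is selected by the silhouette method over a candidate range (default
2–8): for each k, a seeded k-means fit (25 random restarts; `stats::kmeans`
with a fixed master seed — restarts serve the same robustness purpose as
k-means++ seeding while keeping the standard R implementation) and the
mean silhouette width in the retained PCA space, subsampled to at most
10,000 tiles when larger (the silhouette's O(n²) distance matrix is the
only quadratic step in the pipeline). Ties break toward smaller k.

Clusters are then named from their mean raw marker proportions, in rule
order: the cluster whose MUC16 mean is maximal across clusters *and*
dominant within the cluster (≥ 1.5× every other subtype marker mean;
threshold configurable) is Basal.MUC16; S100A2 likewise gives
Basal.S100A2; among the rest, the cluster maximizing the mean classical
signal (CLDN18, GATA6, TFF1) is Classical; a remaining cluster with KRT17
as top marker and low classical mean (< 0.2) is Intermediate. When
clusters remain unnamed while names remain unused — typically merged
clusters at small k — each leftover takes the best-matching unused name
under a relaxed rule without the dominance requirement; `Unassigned`
appears only when there are more clusters than names. Names, not cluster
indices, are the contract: all downstream code is invariant to index
permutation.

## Composition, presence and predominance

Per tumor (or per tumor–slide pair, for shift analysis), the phenotype
proportions over labeled tiles are reported with strict presence calls
(> 1%; at exactly 1% a phenotype is absent — the threshold exists to
absorb detection artifacts) and a basal-present flag on the summed basal
proportion. The predominant phenotype is the argmax even when below 50%
— a majority below one half is common and scientifically meaningful — with
a separate strict > 50% flag preserving the predominance definition; ties
break in the fixed order Classical, Intermediate, Basal.MUC16,
Basal.S100A2.

## Statistics

*Co-occurrence.* For each of the six phenotype pairs, per-tumor presence
calls form a 2×2 table tested with the two-sided Fisher exact test (point
probabilities ≤ the observed one are summed, with a 1e-7 relative tie
tolerance), BH-adjusted across the pairs. The unit of analysis is the
tumor: tile-level 2×2 tables would pseudo-replicate thousands of
correlated tiles per tumor, so the tumor-level reading is the default (a
tile-level mode exists for exploration and is labeled as such). The sample
odds ratio ad/bc is reported and flagged undefined on degenerate margins
(p = 1 in that case).

*Shifts.* Tumors with ≥ 2 slides contribute to the shift denominator; a
shift is a disagreement in predominant phenotype between slides.

*Survival.* Kaplan–Meier curves with median survival (undefined when the
curve never reaches 0.5), the standard log-rank test, and Cox
proportional-hazards regression (Breslow ties) with the six binary
clinicopathological covariates: age > 65, resection margins, vascular
embolism, lymph-node invasion, vascular invasion, perineural invasion.
Constant covariates and designs with fewer events than covariates error
out rather than returning fragile estimates; convergence warnings
(separation/collinearity) are promoted to errors with a diagnostic.

*Scorer concordance.* Pearson correlation between two raters' H-scores by
default (the published figure does not name the coefficient; Pearson is
the natural choice for a 0–300 interval scale), Spearman as an option.

## Marker triage

The triage layer mirrors the multistep antibody selection: (1) in-silico
screening — Pearson r of marker expression against a continuous subtype
signature score, and Mann–Whitney AUC against the binary subtype label
(each marker is oriented with its own subtype as the positive class, so
informative markers score AUC > 0.5); (2) the TMA specificity rules —
(i) ≥ 50% of target-subtype cases at moderate/strong intensity, (ii) lack
of expression in the opposite subtype, (iii) no stromal expression;
(3) the IHC–RNA concordance rule — keep a marker only when the H-score
versus mRNA correlation is significant at α = 0.05.

Rule (ii) is printed as "less than one strong expression or less than two
moderate expressions", which is genuinely ambiguous. The package
implements the conjunction (0 strong AND ≤ 1 moderate) as the default —
the stricter reading, consistent with the phrase "lack of expression" and
with specificity-over-sensitivity intent — and offers the disjunctive
reading behind `ruleTwoDisjunctive = TRUE`.

# The synthetic-data generator

No public pixel or cohort data accompany the method, so the generator is a
first-class module producing every input with planted ground truth.

*Tile tables.* Each phenotype has a profile of expected positive-pixel
fractions; per tile, proportions are drawn from a mean-parameterized Beta
(concentration 50 by default; `Inf` gives noise-free draws equal to the
means). The default catalog reproduces the qualitative marker ordering of
the published phenotypes — Classical high in CLDN18/GATA6/TFF1,
Intermediate KRT17-high with low-moderate GATA6, Basal.MUC16
MUC16-dominant with moderate KRT17, Basal.S100A2 S100A2-dominant with
moderate PanBS, PANCK high throughout — the numeric means are package
defaults, not measured values, because no per-cluster means are published.

*Slide stacks.* Rectangular (or polygonal) regions each carry one
phenotype; within a region, channel pixels are Bernoulli draws at the
profile mean, or, in `pixelNoise = "exact"` mode, a deterministic 10×10
ordered-dither pattern realizing the mean exactly (quantized to 1/100) in
every aligned block — this is what makes "noise-free quantification equals
the planted means exactly" a testable identity. Channels are grouped onto
physical slides following the actual staining plan (PANCK alone, three
duplexes, MUC16 alone) and displaced by planted per-slide rigid
transforms.

*Cohorts.* Each tumor draws which phenotypes it contains (independent
Bernoulli; defaults Classical 0.74, Intermediate 0.96, each basal 0.40,
chosen to match the published cohort's ~74% classical-expressing, 96%
intermediate-expressing and 64% basal-present fractions), then a Dirichlet
composition over the contained phenotypes (concentration 6). A pure
full-support Dirichlet was rejected: it makes basal presence essentially
universal, destroying the contrast that both the survival analysis and any
planted-effect recovery need. Survival times are exponential — constant
hazard, chosen for analytic tractability: the planted hazard ratio is then
exactly the Cox estimand — with baseline 0.02 events/month (median ≈ 35
months, resected-PDAC scale) multiplied by the planted hazard ratio when
the basal proportion strictly exceeds 1%. Censoring is an independent
exponential calibrated so the marginal censoring probability equals the
configured rate; covariates are independent Bernoulli draws at realistic
prevalences with no planted effect.

What the generator does *not* emulate: stain color and texture, tissue
deformation (only rigid offsets), spatial autocorrelation of phenotype
regions within the tile table, segmentation/classifier noise, or
covariate–outcome confounding. Passing recovery tests therefore
demonstrates the correctness of the computational chain under its own
assumptions, not the biological performance of the panel on real slides.

# Numerical choices and degenerate inputs

- Strict `>` at every published threshold (10% PANCK, 1% presence, 50%
  predominance, 5% explained variance), matching the printed wording
  "more than / greater than".
- PCA sign convention: largest-magnitude loading positive per component.
- k-means ties in silhouette selection break toward smaller k;
  composition argmax ties break in the canonical phenotype order.
- Empty or zero-variance tile tables, empty masks, zero-size search
  spaces, constant covariates, single-class labels and length-2
  concordance inputs all raise errors naming the offending input.
- Tumors with zero labeled tiles are excluded from composition with a
  warning; degenerate Fisher margins report p = 1 and an undefined odds
  ratio rather than a number.

# Problem sizes

The test-suite and acceptance workloads use desk-scale sizes chosen to
exercise every code path with comfortable statistical margins: 5,000 tiles
for cluster-count and label recovery, cohorts of 300–500 tumors (100
replicates for null coverage), 200×200 px masks for registration, and a
two-region 120×240 px stack for the end-to-end identity. The pipeline
itself has no scale assumptions beyond memory; the only quadratic step
(silhouette) is subsampled past 10,000 tiles.

# Known limitations

- Rigid registration only; real serial sections deform non-rigidly.
- Binary masks are the input contract: the package does not classify
  pixels, so upstream classifier quality is out of its control.
- The phenotype naming rules assume the canonical four-phenotype
  structure; exotic marker combinations fall back to relaxed matching or
  `Unassigned`.
- Cohort-specific published quantities (tile counts, pooled percentages,
  hazard ratios, IHC–RNA correlations) depend on non-public patient data
  and are not reproduced; the package validates the machinery by planted
  ground-truth recovery instead.

# A minimal run

```{r example, eval = FALSE}
cfg <- analysisConfig(seed = 1)
res <- runPipeline("pdac_run", cfg, nTumors = 60, nTilesPerTumor = 60)
res$kSelection$k           # silhouette-selected number of tile phenotypes
res$pooled$grouped         # pooled basal / classical / intermediate mix
res$cox                    # multivariate Cox table incl. basal presence
```
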