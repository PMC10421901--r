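---
title: "Computational texture mapping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computational texture mapping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctmap)
```

## The problem

Whole-slide H&E images in multi-centre cohorts (TCGA being the canonical
example) are tiled and classified upstream into a small set of tissue
textures — here cancer, normal, stroma, blood, other, plus empty background —
and, per tile, a continuous lymphocyte score in $[0,1]$. Two batch effects
contaminate any naive per-sample lymphocyte summary:

1. **Sampling convention.** Some clinical centres excise blocks spanning the
   tumour border into surrounding normal kidney; others sample the tumour
   core only. Because lymphocyte density differs strongly by texture, the
   raw mean score per sample reflects *what tissue was sampled* as much as
   the patient's immune state.
2. **Stain intensity.** The haematoxylin:eosin balance differs by centre and
   shifts the classifier's score scale multiplicatively.

ctmap operates entirely downstream of the classifiers: its inputs are
long-format tile tables, not images.

## Texture-map smoothing

Classified maps are tessellated: cancer fields are speckled with isolated
tiles of other classes. `pool_map()` slides a $w \times w$ window (default
$3 \times 3$, stride 2) over the texture grid in raster order and reassigns
each visited window to its modal texture. Ties are resolved by a fixed
hierarchy — cancer beats any tie partner; stroma beats anything except
cancer; all remaining ties are drawn uniformly at random — reflecting that
cancer and stroma dominate genuinely mixed tiles. Window counts always come
from the pre-smoothing map (a single pass over one input), final window
offsets are clamped to the map edge so every tile is covered, and where
stride < window the later window in raster order wins. This in-place variant
preserves the map shape, so downstream area accounting is unchanged; a
`mode = "downsample"` variant emitting one tile per window is provided
because the stride-2 description is also consistent with that reading.
Random ties draw from an RNG seeded per sample from (global seed,
sample id), and the tied set is sorted before the draw, so cohort runs are
bit-reproducible regardless of how window counts were accumulated.

## Tumour margin

The margin is the band of non-cancer *tissue* tiles within Chebyshev
distance `depth_tiles` (default 2) of any cancer tile — a square
maximum-filter dilation of the cancer mask, minus the mask, intersected with
tissue. At the default geometry (256 px tiles, 0.25 µm/px) the band is
512 px ≈ 128 µm wide, roughly a dozen lymphocyte diameters. Empty tiles are
never margin: the margin is meant to carry texture composition, and
background carries none. Remaining tissue is non-margin. Margins are
extracted from the pooled map, smoothing being the first post-processing
step. Margin analyses are restricted to samples with ≥ 1 % normal texture
(inclusive bound), since a core-only section has no meaningful exterior.

## Composition, QC and N± stratification

`texture_composition()` reports per-texture tile counts and proportions.
The default denominator is tissue area (empty excluded); whether published
per-sample texture percentages include background in the denominator is
genuinely ambiguous, so the alternative is exposed as
`denominator = "all_tiles"`. Quantitative QC (`apply_qc()`) excludes, in
order: samples scanned outside the accepted resolution band (default
0.1–0.4 µm/px, so ~0.25 passes and ~0.50 fails), samples with < 5 % cancer
texture (strict inequality; 5 % exactly is kept), and samples from manually
excluded centres. Each sample is reported once with its first matching
reason, so kept + excluded always partitions the cohort. `stratify_n()`
labels samples N+ (≥ 1 % normal texture, sampling spans the border) or N−
(< 1 %, core-only); the two strata are analysed separately because their
compositions answer different questions.

## Lymphocyte harmonisation

Per texture $t$ in $T = \{$blood, cancer, normal, stroma, other$\}$, the
density $d_t$ is the mean lymphocyte score over tiles of that texture. The
**relative lymphocyte proportion** rescales the densities to a composition:

$$\rho_t = 100 \cdot \frac{d_t}{\sum_{u \in T} d_u} \quad (\%)$$

so $\sum_t \rho_t = 100$ over the defined textures. $\rho$ is invariant to
any multiplicative stain bias, which cancels in the ratio. The
**harmonised infiltration index** is the area-weighted mean

$$\alpha = \frac{\sum_{t}^{T} \rho_t A_t}{\sum_{t}^{T} A_t}$$

with $A_t$ the texture's area (tile counts and px² give identical $\alpha$,
the units cancelling), hence $\min_t \rho_t \le \alpha \le \max_t \rho_t$
always. Textures absent from a sample contribute zero area and vanish from
both sums; a texture with tiles but below the `min_texture_tiles` floor
(default 1, i.e. no floor) gets $\rho = 0$ and is flagged.

Two readings of $\rho$ are defensible: computed per sample from that
sample's own densities, or computed once at cohort level from per-texture
median densities and applied to every sample's areas. The per-sample form
is the default (`rho_source = "per_sample"`) because it needs no cohort
state and degrades gracefully for samples lacking textures; the
cohort-median form (`"cohort_median"`) is the one matching rescaled
cohort-level figures and is a switch away.

Residual centre effects are absorbed by `centre_binarise()`: within each
centre holding at least `min_centre_n` samples (default 21, i.e. more than
20 — smaller batches make the centre median itself unstable), a sample is
High if its value exceeds the centre median, Low otherwise (ties Low, a
strict rule so High never exceeds ⌈n/2⌉). Samples in smaller or manually
excluded centres are left unclassified rather than pooled across centres.
Whether the binarised value should be $\alpha$ or the raw total density is
left to the caller (`binarise_on` in the pipeline); both are computed.

## Margin enrichment

`margin_profile()` compares margin and non-margin regions: texture
composition within each region (tissue denominator, so each sums to 1),
per-texture and total lymphocyte densities, and margin:non-margin ratios.
Zero denominators yield `NA` rather than a pseudocount, because a
pseudocount silently manufactures enrichment exactly where data are
sparsest; a `pseudo = TRUE` add-one-tile option exists for users needing
finite ratios. Swapping the two regions inverts every defined ratio.
`enrichment_classes()` splits ratios at a cohort quantile (default the
median, the standard Kaplan–Meier split; the split point uses R's type-7
linear-interpolation quantile).

## Association statistics

`associate()` dispatches: numeric vs 2 groups → unpaired two-tailed
Wilcoxon rank-sum; vs ≥ 3 groups → Kruskal–Wallis; categorical pairs → χ²
(uncorrected by default, Yates optional). The Wilcoxon p is exact when the
combined n ≤ 20 with no ties, otherwise a tie-corrected normal
approximation; fully tied data (zero rank variance) report the null
boundary p = 1 directly rather than the 0/0 the tie correction produces.
`adjust_bh()` wraps the standard step-up Benjamini–Hochberg correction,
with one family per feature screen. `survival_logrank()` administratively
censors at a 60-month horizon (5-year overall survival) before fitting
Kaplan–Meier curves and the log-rank test via the survival package. The
test suite cross-checks each of these against independent oracles:
exhaustive permutation for Wilcoxon, the explicit step-up formula for BH,
and a hand-coded O−E sum for the log-rank statistic.

## The synthetic cohort generator

`generate_cohort()` produces the ground-truthed inputs every stage is
tested on. Each sample is an elliptical cancer core (jittered semi-axes) in
an empty border; N+-style samples wrap the core in a stroma ring and an
outer normal rim, N−-style samples fill the non-core with a
stroma/blood/other mixture drawn from per-centre Dirichlet concentrations
and contain no normal tissue. Blood/other speckles (rate 0.04) are injected
post hoc so pooling has something to smooth. Scores per tissue tile are
$\mathrm{clip}(b_c\, e_t + \varepsilon,\, 0,\, 1)$ with shared enrichment
$e_t$, per-centre lognormal stain bias $b_c$ and Gaussian tile noise
$\varepsilon$ — the simplest noise model respecting the score range.

Defaults were chosen once to mirror the cohort features the method targets:
4 centres × 25 samples on 48 × 48 grids (256 px tiles at 0.25 µm/px);
N+ sampling probability spread 0.95/0.70/0.35/0.05 across centres
(centre-specific conventions); enrichment ordered
normal (0.45) > cancer (0.35) > stroma (0.25) > blood (0.15) > other (0.08),
the density ordering typically observed in renal sections; stain bias
sd 0.15 on the log scale; tile noise sd 0.05. Survival is exponential
(baseline median 60 months) with an optional log-linear link to the N+
covariate and uniform administrative censoring at 24–120 months — enough to
exercise the KM/log-rank plumbing, nothing more.

What the generator does *not* emulate: real histology geometry (ellipses,
not infiltrative tumour fronts), spatially correlated score noise,
within-centre protocol drift, or classifier error structure. Passing tests
therefore demonstrate algorithmic correctness and the harmonisation
mechanism under controlled bias, not performance on real slides.

## Numerical and degenerate-input choices

- Coordinates are 0-based (row, col), top-left origin, row-major; tiles
  absent from a sparse file but inside the declared bounding box are empty.
- Maps smaller than the pooling window are returned unchanged with a
  warning; all-empty maps are flagged rather than erroring.
- All-zero densities give a flagged uniform $\rho$; a zero total area is an
  error for $\alpha$.
- Ties at the centre median are Low; ties in pooling follow the
  cancer/stroma hierarchy and then a seeded uniform draw over the sorted
  tied set.
- Problem sizes in the test suite are scaled to what the properties need:
  pooling and margin oracles run on ≥ 100 random maps up to 12×12 and
  15×15; the harmonisation property uses 100 seeded replicates of
  two-centre cohorts (8 samples/centre, 32 × 32 grids) with N+ probability
  0.95 vs 0.05.

## Known limitations

$\alpha$ is stain-free by construction but not perfectly composition-free:
it weights $\rho$ by the sample's own texture areas, so cohorts whose
centres differ extremely in composition retain a small systematic
$\alpha$ gap. In the simulation study this shows up as the ~2–5 % of
replicates where a fortuitous stain-bias draw cancels the raw-density gap
between centres while $\alpha$'s residual gap persists — in those draws the
raw between-centre variance is accidentally the smaller one. The
centre-median binarisation exists precisely to absorb such residual
centre-level offsets.

The margin definition is lattice-Chebyshev, matching a square maximum
filter; it is not a Euclidean or geodesic distance, and a margin crossing
an empty region (torn tissue, slide edge) is truncated to tissue tiles.
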