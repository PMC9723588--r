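# betabrowning

Nonmonotonic responses of lake bacterial communities to freshwater
**browning** — the rise of terrestrially derived colored dissolved organic
matter (CDOM) — and the **thresholds** ("guardrails") that separate
alternative community trajectories along the browning gradient.

`betabrowning` is for microbial ecologists who have a site-by-taxon (ASV)
count table and one or more browning descriptors per site (TOC in
mg C L⁻¹, a_CDOM in absorbance units, or full 400–750 nm absorption
spectra) and want to ask: *does community composition shift smoothly with
browning, or does it jump at particular browning values?*

## The method

The core object is a **beta-diversity response surface**. For every pair
of sites *(i, j)* the Bray–Curtis dissimilarity
*d(i, j) = Σ|xᵢₖ − xⱼₖ| / Σ(xᵢₖ + xⱼₖ)* is regressed on the browning
values of the two sites,

&nbsp;&nbsp;&nbsp;&nbsp;*d(i, j) ≈ f(gᵢ, gⱼ)*,

with gradient-boosted regression trees (squared loss, second-order leaf
weights *Σr/(n+λ)*), a random forest, a feed-forward neural network
(ReLU, Xavier initialisation, MSE loss) and an OLS-by-SVD polynomial as
the monotonic baseline. The fitted *f* is predicted over a meshgrid whose
step is the smallest pairwise gradient difference. Reading the surface
**next to its diagonal** gives the community turnover profile *t(g)*:
local maxima of *t* ("ridges") are browning thresholds where composition
shifts more than average; minima ("valleys") are stable regimes. The
*R²* contrast between the boosted trees and the degree-1 polynomial
quantifies how much of the community response is invisible to monotonic
models.

Individual taxa are screened with **MINE statistics**: the maximal
information coefficient (MIC, the maximum normalised mutual information
over grids with bounded cell count *a·b ≤ n^0.6*) measures the strength of
the abundance–gradient relationship, and the maximum asymmetry score
(MAS = max |M[a,b] − M[b,a]|) measures its deviation from monotonicity.
Significant taxa (permutation *q* < 0.05, MIC ≥ 0.3) with MAS < 0.05 are
monotone, the rest nonmonotone.

Alpha-diversity estimators (richness, Shannon, Simpson, Fisher's α, ACE
with explicit Chao–Lee components), rarefaction, exact species
accumulation, RDA variance partitioning, distance decay and a
linear-vs-quadratic hump test complete the monotonic side of the
comparison. A seeded synthetic-community generator with known regime
thresholds (`simulate_browning_dataset()`) makes the whole pipeline
testable end to end.

## Worked example

```r
library(betabrowning)

ds <- simulate_browning_dataset(seed = 1)   # the standard synthetic scenario
ds
#> Synthetic browning dataset: 80 sites x 340 taxa
#>   gradient:  0.00622 11.45819  thresholds: 3, 7

g     <- ds$site_table$gradient_value
pairs <- build_pair_dataset(g, bray_curtis(ds$counts))
folds <- split_train_test(pairs, seed = 1)

fit <- fit_gradient_boost(folds$train)      # 300 rounds, depth 3, nu = 0.1
evaluate_model(fit, folds$test)
#> gbt: train MSE 0.01608 / R^2 0.686 | test MSE 0.01789 / R^2 0.642
evaluate_model(fit_polynomial(folds$train, 1), folds$test)
#> polynomial: train MSE 0.05116 / R^2 0.001 | test MSE 0.0501 / R^2 -0.002

surf <- predict_meshgrid(fit, g)
surf
#> Mesh surface (gbt): 500 x 500, step 0.02295, baseline 0.5095
report <- detect_ridges_valleys(turnover_profile(surf))
report
#> Threshold report (baseline 0.238):
#>   ridges : 0.098, 3.01, 7.05
#>   valleys: none
```

What the numbers mean: the boosted trees explain 64% of the held-out
pairwise dissimilarity while the linear surface explains none — the
community's response to browning is almost entirely nonmonotonic. The
surface baseline (0.51) is the typical between-site dissimilarity; the
turnover profile's ridges at **3.01** and **7.05** recover the
generator's true regime thresholds (τ = 3 and 7) to within the meshgrid
resolution; the additional near-edge feature at 0.098 illustrates why
features close to the gradient ends deserve skepticism. `mine_screen()`
applied to the same dataset classifies taxa as monotone or nonmonotone,
and `variance_partition()` / `alpha_hump_test()` supply the monotonic
baselines.

`run_pipeline()` orchestrates simulate → alpha → MINE → surface →
thresholds → variance partitioning with one seed and writes every
artifact as TSV/JSON plus a run manifest;
`inst/cli/browning-pipeline.R` is a thin command-line wrapper.

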