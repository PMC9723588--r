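---
title: "Detecting nonmonotonic community thresholds along browning gradients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting nonmonotonic community thresholds along browning gradients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Freshwater browning — the rise of terrestrially derived colored dissolved
organic matter (CDOM) in lakes — restructures bacterioplankton communities,
but not monotonically. Association methods that assume monotone responses
(linear regression, RDA, variance partitioning) can explain only a few
percent of compositional variance along browning gradients, while flexible
regressors that admit non-monotonicity explain an order of magnitude more.
More importantly, nonmonotonic models locate *thresholds*: browning values
at which community composition shifts abruptly, separating alternative
community trajectories ("guardrails" between "valleys").

`betabrowning` implements this analysis as a reusable, testable pipeline:

1. **Beta-diversity response surfaces.** Pairwise Bray–Curtis distances
   `d_ij` between sites are regressed on the browning values `(g_i, g_j)` of
   the two sites, with gradient-boosted regression trees (the reference
   model), a random forest, a small feed-forward neural network, and an
   OLS polynomial baseline. The fitted model is predicted over a meshgrid
   spanning the gradient and read near its diagonal.
2. **Threshold detection.** Local maxima of the near-diagonal turnover
   profile are reported as ridges (thresholds); local minima as valleys
   (stable regimes).
3. **Per-taxon screening.** MINE statistics — the maximal information
   coefficient (MIC) and the maximum asymmetry score (MAS) — classify each
   taxon's abundance–gradient relationship as monotone or nonmonotone.
4. **Monotonic baselines.** RDA R², variance partitioning into unique and
   shared adjusted-R² fractions, distance decay with a Mantel permutation
   test, and a linear-vs-quadratic AIC test for the alpha-diversity hump.
5. **A synthetic-community generator** with known regime thresholds, which
   is what makes every stage falsifiable without field data.

## The synthetic scenario and what it emulates

The *standard synthetic scenario* — the configuration used throughout the
package's validation — is 80 sites with browning values drawn uniformly on
[0, 12] (the scale of boreal-lake TOC in mg C L⁻¹), 300 gradient-response
taxa, regime thresholds at τ = 3 and 7, two alternative community states in
each segment below the convergence level of 7, and a constant multinomial
sequencing depth of 10,000 reads per site.

```{r}
library(betabrowning)
ds <- simulate_browning_dataset(seed = 1)
ds
```

Each taxon's expected abundance follows one of four response shapes:
logistic increase or decrease, Gaussian (unimodal), or a sharp logistic
step at a regime threshold (width 1% of the gradient range — a
differentiable stand-in for a discontinuity that keeps expected profiles
smooth). The default mix is 20% up, 20% down, 50% unimodal, 10% step.
Three structural choices matter and were made once, on ecological grounds:

* **Monotone taxa are broad, abundant generalists** (logistic widths of
  one half to one full gradient range, log-normal amplitudes with
  `meanlog = 0`). Consequently community dissimilarity between *distant*
  sites is dominated by regime structure rather than by smooth species
  turnover — matching the empirical observation that gradient separation
  per se explains little Bray–Curtis variance along browning gradients.
* **Unimodal taxa are narrow-niche, low-abundance specialists** (widths
  R/10–R/4, amplitudes an order of magnitude lower, optima drawn from a
  Beta(2, 2) density peaked mid-gradient). They control presence/absence
  richness — producing the hump of alpha-diversity at intermediate
  browning — while carrying little weight in the abundance-based
  Bray–Curtis distance.
* **Alternative states are disjoint indicator-taxon blocks.** Sites below
  the convergence threshold are randomly assigned one of two states per
  segment; a site's state block receives 50% of its expected relative
  abundance (the top of the 30–50% band within which the threshold signal
  is detectable but not trivial). State mismatch is binary: any two sites
  in different states differ by the full block, whether they are in
  adjacent segments or far apart. How alternative states manifest
  compositionally is not observable from survey data; this block
  construction is our operationalisation and tests should be read
  accordingly.

What the generator does **not** emulate: phylogenetic structure (no trees,
so no UniFrac or Faith's PD), chimeras and sequencing error, spatial
autocorrelation, unequal sequencing depth (depth is constant so that
rarefaction is exercised explicitly by subsampling), and taxon–taxon
interactions. Passing tests therefore demonstrate that the *procedures*
recover the structures they target under a known, plausible generative
model — not that any particular field system contains those structures.

## Reading thresholds off the surface

`predict_meshgrid()` spans the gradient from minimum to maximum with a step
equal to the smallest positive pairwise difference between site values,
capped at 500 points per axis (the step rule is unbounded when two sites
nearly coincide; the cap inflates the step with a warning). Because a
pairwise dissimilarity is symmetric by definition, each mesh cell averages
the model prediction over both argument orders — greedy tree ensembles
otherwise drift away from exchange symmetry (deterministic tie-breaking
prefers the first feature, and the asymmetry grows with boosting rounds
rather than averaging out). The mean of the
off-diagonal cells is the *baseline beta-diversity*. `turnover_profile()`
averages, at each axis position, the predicted distance over the `band_k`
(default 3) cells on either side of the diagonal — the formal version of
"looking at a point bordering the diagonal".

```{r}
g <- ds$site_table$gradient_value
pairs <- build_pair_dataset(g, bray_curtis(ds$counts))
fit <- fit_gradient_boost(pairs)
surf <- predict_meshgrid(fit, g)
report <- detect_ridges_valleys(turnover_profile(surf))
report
plot(surf)
```

`detect_ridges_valleys()` reports ridges as local maxima of the turnover
profile with (i) peak prominence at least `min_prominence_frac` (default
0.1) of the profile's range, and (ii) turnover above the reference level;
valleys are the mirror image. Two detector choices deserve explanation,
because the visual reading they formalise has no canonical quantitative
rule:

* **The ridge gate compares turnover to the *profile's own mean*, not to
  the global surface mean.** With a band of half-width k, the turnover at
  a true threshold is at most the average of the within-segment and
  cross-segment dissimilarity, `(W + C)/2`, because at most half of the
  band straddles the threshold. The global surface mean, by contrast, is a
  cross-pair-dominated average (about 65% of site pairs cross at least one
  threshold in the standard scenario), so `t > surface mean` would require
  `W > C` — impossible whenever crossing a boundary increases
  dissimilarity. Gating on the *average near-diagonal shift* instead reads
  "a shift greater than average" on the quantity actually being profiled,
  and is what makes recovery of known thresholds possible at all. The
  surface mean is still computed and reported (`surface_baseline`) as the
  baseline beta-diversity.
* **A flat profile yields an empty report.** The profile counts as flat
  when its range is below `flat_tol` (default 0.25) times the surface
  baseline: if near-diagonal turnover varies by less than a quarter of the
  typical between-site dissimilarity, its wiggles are model noise, and
  promoting them to thresholds would be spurious. This rule is what keeps
  the false-positive rate on regime-free (purely monotone) gradients at
  zero; it is scale-invariant, which is the meaningful invariance for a
  dissimilarity (a ratio-scale quantity — an additive offset of a
  Bray–Curtis value has no interpretation).

Extrema at the axis ends are reported with `edge = TRUE` and should be
discounted: their bands are one-sided, and a monotone profile always ends
on a maximum. Features closer than `min_separation_frac` (default 0.05) of
the gradient range merge into the more prominent one.

## Surface models

All four models share the `beta_surface` S3 interface (`predict`,
`fitted`, `residuals`, `summary`, `plot`; `coef` for the polynomial).
Mirrored pairs — both orderings of every site pair are included by default
— are always kept in the same train/test fold, otherwise the identical
target value would leak across folds. Site-level non-independence of pairs
(every distance shares its sites with 2(n−2) others) is acknowledged and,
as in standard practice for this design, ignored by the default splitter.

* **Gradient boosting** (`fit_gradient_boost`): squared loss, so the
  second-order (Newton) leaf weight is `sum(residuals)/(count + lambda)`;
  defaults rounds = 300, depth = 3, learning rate ν = 0.1, leaf penalty
  λ = 1; base score = training mean. Training MSE is provably
  non-increasing per round for λ ≥ 0 and ν ∈ (0, 1], and the per-round path
  is stored. Trees and their predictions are compiled code; a single
  depth-1 tree reproduces the exhaustive best-SSE split.
* **Random forest** (`fit_random_forest`): fully grown trees (nodes of
  ≥ 5 rows may split) on bootstrap resamples, prediction = mean of trees.
* **FFNN** (`fit_ffnn`): 2–16–16–1 by default, ReLU hidden layers, linear
  output, Xavier-uniform initialisation (|w| ≤ √(6/(fan_in+fan_out))),
  MSE loss, plain mini-batch gradient descent (batch 32, rate 0.01,
  500 epochs), inputs z-scored. Divergence (non-finite loss) raises an
  error naming the epoch.
* **Polynomial** (`fit_polynomial`): OLS by SVD on all monomials
  `g1^a g2^b`, `a+b ≤ degree`; singular values below `rcond` (1e-10) times
  the largest are dropped. `select_degree()` chooses the degree on a
  bootstrap bias–variance decomposition; with population variances the
  identity `error = bias² + variance` holds exactly, the squared-bias term
  being taken against observed targets and therefore absorbing the noise
  floor. Ties go to the lowest degree.

`evaluate_model()` reports MSE and R² per fold, with R² computed against
the evaluated fold's own mean on raw (unstandardised) distances. A
zero-variance test target leaves R² as `NA` with a warning (the MSE is
still returned).

## MINE statistics

The characteristic matrix entry for a grid with `a` x-bins and `b` y-bins
(`a·b ≤ B(n) = floor(n^0.6)`) is the best achievable mutual information
normalised by `log2(min(a, b))`. With one axis's partition fixed,
maximising MI over the other axis is equivalent to minimising the additive
column cost `Σ_c M_c H(row | c)` — a one-dimensional partition dynamic
program over *clumps* (runs of equal x, and consecutive points sharing a
row, which an optimal partition never separates; capped at
`clump_factor × columns` superclumps, default 15). The DP is exact given
the clumps; the package's tests verify it against exhaustive enumeration.
Each matrix entry takes the better of the two orientations (equipartition
y / optimise x, and the reverse) — this is what makes MAS = 0 for
noiseless monotone data while a noiseless parabola keeps MAS well above
the 0.05 monotonicity cutoff.

Significance is by seeded permutation of the gradient with the add-one
convention `p = (1 + #{MIC_perm ≥ MIC_obs})/(n_perm + 1)` — exact-level by
construction; the original MINE tables are precomputed null quantiles and
the source analysis does not say which null it used, so the self-contained
permutation null is the default. "FDR as determined by Hochberg" is read
as Benjamini–Hochberg (that is what q-values are); the family-wise
Hochberg step-up is available via `fdr_method = "hochberg"`. A taxon is
*monotone* when significant (q < 0.05, MIC ≥ 0.3) with MAS strictly below
0.05, *nonmonotone* when significant otherwise.

Two subtleties, verified in the test suite:

* MAS is computed from rank-based grids, so it measures monotonicity of
  the relationship in *rank space*; tiny absolute wiggles inside a dense
  cluster of y-values are real nonmonotone structure to MINE.
* Compositional closure matters. Dividing by the (gradient-dependent)
  community total can make the relative abundance of a genuinely monotone
  taxon nonmonotone. The shape-recovery validation therefore screens the
  noiseless expected responses themselves (`normalize = FALSE`), scoring
  unimodal taxa only when their optimum is interior to the gradient range
  by at least one response width — a unimodal response with an edge
  optimum *is* monotone over the sampled range.

## Monotonic baselines

`rda_r2()` is the trace R² of the multivariate regression of the centred
(typically Hellinger-transformed) community matrix on scaled predictors,
with the Ezekiel adjustment. `variance_partition()` applies
inclusion–exclusion over the adjusted R² of every subset union of 2–3
predictor sets (negative adjusted fractions are reported, not clipped;
with `adjusted = FALSE` the decomposition is exact to machine precision).
`distance_decay()` fits OLS on the unordered pairs and permutes rows and
columns of the geographic matrix jointly (999 permutations by default,
one-sided for positive slope). `alpha_hump_test()` is the documented
parametric stand-in for spline smoothing: degree-1 vs degree-2 OLS
compared by `AIC = n log(SSE/n) + 2k`, with a peak reported only for a
concave fit with an interior vertex. Spline machinery (GAMs, ordination
surface smoothers) is deliberately out of scope; the quadratic test
preserves the testable claim — an interior optimum — without it.

## Diversity estimators

Hellinger, Bray–Curtis, expected rarefaction, subsampling and the exact
species accumulation curve are delegated to vegan (log-gamma binomial
arithmetic included), behind interfaces that add the contracts this
pipeline needs: hard errors on zero rows, on depths exceeding a site's
reads (the default depth is the minimum row sum, the common-depth rule),
and on undefined distances. ACE and Fisher's α are implemented directly so
that components (`S_rare`, `F1`, `C_ace`, γ²) are returned and degenerate
cases fail loudly: when every rare taxon is a singleton the coverage
estimate is zero and ACE is *undefined* — the estimator raises rather than
silently substituting another estimator, because silent estimator swaps
corrupt cross-site comparisons. Shannon entropy uses the natural log
(configurable base); both Simpson conventions (1−Σp², 1/Σp²) are reported
to disambiguate "Simpson diversity". The CDOM PCA index standardises the
absorption spectra (400–750 nm at 1 nm), and PC1 is oriented to correlate
positively with mean absorbance so the browning index direction is
reproducible.

## Reproducibility and problem sizes

Every stochastic step takes a seed; `run_pipeline()` fans one global seed
out to per-stage seeds by a fixed affine map (`seed × 97 + stage`), so
stage-level reruns reproduce byte-identical TSV/JSON artifacts. The test
suite validates threshold recovery and the false-positive control on 20
simulated surveys each at the full standard scenario; Monte-Carlo oracles
use 2,000–10,000 replicates; the permutation-null calibration uses 1,000
independent pairs at n = 100 with 199 permutations; MINE's DP is checked
against exhaustive search on 100 instances with n ≤ 12. These sizes give
the binomial/KS margins quoted in the tests comfortable slack while
keeping the whole suite runnable on a laptop.

## Known limitations

* The ridge/valley rule formalises a visual reading; its constants
  (band width, prominence, separation, flatness tolerance) are exposed in
  the API and defaults were chosen on the synthetic scenario. Real surveys
  with very different pair-distance distributions may need different
  settings, and detected ridge *positions* inherit the meshgrid
  resolution.
* Pairwise distances are not independent observations; R² values on pair
  folds are optimistic in the usual way. A site-blocked splitter would be
  the conservative alternative and the default split should be read with
  that caveat.
* The MINE implementation uses the published approximation (equipartition
  one axis, optimise the other over clumps); it is exact for the DP
  subproblem but, like every MINE implementation, a lower bound on the
  true grid optimum.
* ACE is undefined (by design, loudly) when all rare taxa are singletons;
  Fisher's α requires 1 < S < N.
* The generator's alternative-state construction is one of many ways
  "alternative stable states" could look compositionally; threshold
  recovery rates are conditional on it.
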