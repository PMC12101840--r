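---
title: "Category structure, cross-modal alignment, and word learnability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Category structure, cross-modal alignment, and word learnability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lexalign)
```

## The scientific question

Children typically learn concrete nouns before verbs. One family of
explanations (the Natural Partitions Hypothesis) holds that nouns label
naturally individuated referents, while verbs label relational event
categories that are harder to carve out. `lexalign` operationalizes three
quantitative ingredients of that debate on embedding data:

1. **Category structure within a modality.** For each word category with
   exemplar vectors in an embedding space, *variability* is the mean
   Euclidean distance from exemplars to the category centroid, and
   *discriminability* is the mean Euclidean distance from all other
   categories' exemplars to that centroid. Diffuse, overlapping verb
   categories should score high on the first and low on the second.
2. **Cross-modal alignment.** Whether the relational structure of word
   meanings agrees between vision and language is measured by *alignment
   strength*: the Spearman rank correlation between the upper triangles of
   the two modalities' pairwise cosine-similarity matrices (a second-order,
   RSA-style statistic). Its permutation percentile — the fraction of
   randomly misaligned word mappings scoring strictly lower — is the
   *relative alignment strength*.
3. **Learnability.** A gradient-boosted regression predicts each word's age
   of acquisition (AoA, the age in months at which half of children
   understand the word) from frequency, word type, the category-structure
   metrics, and alignment, and exact tree-Shapley values attribute the
   prediction to the features.

The package consumes embedding tables (one exemplar vector per row) from any
source; it deliberately does not extract embeddings from images or text
itself.

## The alignment statistic and its null

Given one representative vector per word and modality, the
cosine-similarity matrices $S_V$ and $S_L$ are compared by Spearman's
$\rho$ over their $N(N-1)/2$ strictly-upper-triangle entries (average ranks
for ties). The null model permutes the word-to-word mapping: permutations of
$\{1..N\}$ are sampled uniformly with replacement from all permutations
*except the identity*. Fixed points are allowed — we sample misaligned
mappings, not derangements; this is the minimal reading of "randomly
mismatched" and the identity exclusion alone guarantees every draw is wrong
somewhere. Each permutation reindexes the precomputed visual matrix
($S_V[\pi,\pi]$), which is mathematically identical to recomputing cosines
under the permuted pairing (a property the test suite checks exactly) and
costs $O(N^2)$ instead of $O(N^2 d)$.

Relative alignment strength counts permuted mappings *strictly* below the
true mapping; ties count against the true mapping, a conservative choice
that only matters for degenerate (discrete-valued) embeddings.

With $N = 2$ the upper triangle is a single number and rank correlation is
undefined, so similarity matrices require $N \ge 3$. A constant upper
triangle likewise has no defined rank correlation; `alignment_strength()`
returns `NA` with a classed warning rather than guessing.

## Exemplar aggregation

Prototype formation is modeled as arithmetic averaging of $k$ exemplars
sampled without replacement. The one-dimensional curves hold one modality at
a well-learned prototype (by default 20 exemplars, the point at which
prototypes stabilize) and grow the other modality incrementally: within a
simulation each word receives one random exemplar order and the $k$-th curve
point uses the first $k$ exemplars, mirroring a learner accumulating
evidence and keeping per-simulation curves monotone in information. The
fixed modality's prototype is redrawn every simulation so that prototype
uncertainty propagates into the bootstrap confidence intervals (percentile
bootstrap of the simulation means, 1,000 resamples, 95% by default).

The two-dimensional grid treats both modalities symmetrically: each cell
$(k_v, k_l)$ is an independent Monte Carlo mean of relative alignment
strengths with freshly sampled prototypes on both sides.

Full-scale defaults are 1,000 permutations per evaluation, 1,000 simulations
per curve level, and 500 per grid cell; all are `run_config()` fields and
the examples and tests in this package run them at reduced desk scales
(100–200 simulations, 100–200 permutations) chosen so each Monte Carlo
standard error stays well below the effects being asserted.

## The synthetic generator

Real embedding systems for this analysis come from pretrained networks and
are not redistributable, so every stage is exercised against a generator
with known ground truth. Per word $i$, a latent direction
$z_i \sim \mathcal N(0, I_{d_\ell})$ is shared between modalities; each
modality $m$ forms a category direction

$$u_i^m = \sqrt{a}\, M_m z_i + \sqrt{1-a}\, M'_m e_i^m,$$

with $e_i^m$ independent standard normal and $M_m, M'_m$ random orthonormal
maps into the modality space, and draws exemplars
$x_{ij} = s\,u_i^m + \sigma_m \varepsilon_{ij}$ with isotropic Gaussian
noise. Design notes:

* **Orthonormal maps** preserve angles, so at $a = 1, \sigma = 0$ the two
  modalities have *identical* cosine structure and alignment strength is
  exactly 1 — an analytic anchor the tests assert.
* **$\sqrt a$ mixing** keeps the category-direction variance constant in
  $a$, so the mixing weight moves alignment without moving
  discriminability.
* $a = 0$ gives independent modalities: the true mapping is exchangeable
  with permuted ones and relative alignment strength is uniform on $[0,1]$
  across replicate systems — the calibration property the acceptance suite
  checks (mean in $[0.45, 0.55]$, roughly uniform deciles).

The generator reproduces only the statistical structure the measures
consume: isotropic Gaussian clusters with controllable dispersion,
separation, and cross-modal consistency. It does not mimic the anisotropy,
hubness, or frequency effects of real network embeddings, so green tests
certify the *estimators*, not any empirical claim about vision or language.

Two presets encode the qualitative noun/verb contrast: `noun_like`
(separation 1.5, visual dispersion 0.8) and `verb_like` (separation 1.0,
visual dispersion 2.0), with equal mixing weight 0.8 and equal linguistic
dispersion so the contrast isolates visual category structure. Dispersions
and separations were fixed once at values giving single-exemplar relative
alignment visibly below ceiling for the verb-like preset (the regime the
aggregation analyses live in).

The monotonicity acceptance check runs on an aligned system with dispersion
3 relative to separation 1: large enough that one exemplar is far from
ceiling and the aggregation curve spans its rising regime across
$k = 1..8$ instead of saturating immediately.

## The learnability stage

`estimate_aoa()` fits a two-parameter logistic in age to
proportion-knowing curves by Levenberg–Marquardt least squares and reports
its midpoint. A logistic fit is robust to non-monotone sampled proportions
where linear interpolation is not; when the observed proportions never
bracket 0.5 the estimate would be an extrapolation, and the result is
flagged `out_of_range` with `aoa_months = NA` instead.

`fit_aoa_model()` uses XGBoost with squared error, defaulting to 10,000
rounds, depth 10, learning rate 0.02, fitted in-sample with no held-out
split: the model is explanatory — the object of interest is the attribution
pattern, not out-of-sample accuracy. Frequency enters as $\log_{10}$
(the standard transform in AoA work); the raw column is retained but not
modeled. Attributions are exact tree-path Shapley values
(`predict(..., predcontrib = TRUE)`), additive to the prediction for every
word; global importance is the mean absolute attribution per feature, with
the direction of each feature reported as the sign of the rank correlation
between feature value and attribution.

The per-word `alignment` feature is this package's explicit construction
(the system-level statistic has no canonical per-word decomposition): the
Spearman correlation of word $i$'s similarity-matrix row across modalities,
diagonal removed. Outputs label it as such.

## Numerical choices and degenerate inputs

* Embeddings are used as-is — no centering or normalization before distance
  computations; an optional L2-normalization flag exists in the CLI, off by
  default.
* Zero-norm exemplars are rejected at construction (cosine undefined).
* Exemplar counts may differ across words; all formula denominators use
  per-word counts, and discriminability averages within each other category
  before averaging across categories, so categories are weighted equally
  (this reduces to the classic grand-mean form at equal counts).
* The two-sample comparisons are pooled-variance Student t-tests
  (df $= n_1 + n_2 - 2$); zero pooled variance with equal means returns
  $t = 0$, with unequal means it is an error rather than $\pm\infty$.
* Shapley additivity holds to float32 resolution (~$10^{-5}$ on
  month-scale predictions), the precision at which xgboost computes
  contributions.
* One root seed in `run_config()`; each stage derives a labeled substream
  (`derive_seed()`), so any stage reruns identically in isolation. All
  stochastic outputs are bit-reproducible under a fixed root seed.

## Known limitations

* The ensemble's Shapley attributions carry an approximation floor of
  roughly 0.2% of the top feature's importance (independent of residual
  noise and boosting length). Features whose true contribution falls near
  that floor — e.g. the bottom of a geometric effect ladder spanning three
  orders of magnitude — cannot be reliably ranked against a pure-noise
  feature at $n = 400$ words. Parameter-recovery claims should therefore be
  read for effects above the floor; the recovery tests document this regime
  explicitly.
* Relative alignment strength is a percentile, not an effect size: it
  saturates at 1.0 once the true mapping beats every sampled permutation
  and is insensitive to further improvement.
* The aggregation simulations assume exchangeable exemplars within a
  category; real exemplar streams (child-directed speech, visual
  experience) are autocorrelated.
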