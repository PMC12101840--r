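# lexalign

Quantitative tools for a classic question in language acquisition: why are
verbs harder to learn than nouns? `lexalign` is aimed at computational
cognitive scientists who have word-level embedding data — visual exemplar
embeddings and linguistic context embeddings for the same word set — and
want to measure (i) how tight and separable each word category is in each
modality, (ii) how well the two modalities' relational structures align,
(iii) how alignment grows as a learner accumulates exemplars, and (iv) how
these quantities, together with frequency and word type, explain each
word's age of acquisition.

## The statistics at its core

For a system of $N$ words with exemplars $x_{i1},\dots,x_{iK_i}$ per word
$i$ and centroids $c_i = \tfrac1{K_i}\sum_j x_{ij}$:

* **variability** $\;v_i = \tfrac1{K_i}\sum_j \lVert x_{ij}-c_i\rVert$ —
  within-category spread;
* **discriminability**
  $\;d_i = \tfrac1{N-1}\sum_{j\ne i}\tfrac1{K_j}\sum_k
  \lVert x_{jk}-c_i\rVert$ — distance of everyone else from category $i$;
* **alignment strength** $\rho = \mathrm{Spearman}\big(\mathrm{upper}(S_V),
  \mathrm{upper}(S_L)\big)$, where $S_V, S_L$ are pairwise
  cosine-similarity matrices of category representatives — a second-order
  (RSA-style) agreement between modalities;
* **relative alignment strength** — the fraction of randomly permuted
  (misaligned) word mappings, identity excluded, whose alignment strength
  is strictly lower than the true mapping's;
* **AoA regression** — XGBoost (10,000 rounds, depth 10, learning rate
  0.02, squared error) of age of acquisition on word features, explained by
  exact tree-Shapley attributions; global importance is the mean absolute
  attribution per feature.

A synthetic generator produces bimodal Gaussian-cluster systems with
controllable dispersion, separation, and cross-modal mixing, plus
learnability tables with known effect sizes, so every stage is testable
with ground truth. See the vignette
(`vignettes/crossmodal-alignment.Rmd`) for the model and design decisions.

## Worked example

Contrast a noun-like system (visually tight, well-separated categories)
with a verb-like one (diffuse, overlapping), then watch alignment sharpen
as visual exemplars accumulate:

```r
library(lexalign)

noun <- generate_bimodal_system(preset_params("noun_like", n_words = 40, seed = 1))$system
verb <- generate_bimodal_system(preset_params("verb_like", n_words = 40, seed = 1))$system

# verb categories are visually more variable than noun categories
cs_n <- category_structure(noun)$table
cs_v <- category_structure(verb)$table
compare_groups(cs_v$visual_variability, cs_n$visual_variability)
#> t(78) = 120.197, p = 2.66e-90; means 10.94 vs 4.376

# cross-modal alignment of the verb system's centroids, with permutation null
s_v <- cosine_similarity_matrix(system_centroids(verb$visual))
s_l <- cosine_similarity_matrix(system_centroids(verb$linguistic))
alignment_report(s_v, s_l, n_permutations = 1000, seed = 2)
#> Alignment strength rho = 0.5216; relative alignment strength = 1.000 (1000 permutations)

# a learner accumulating visual exemplars, linguistic prototypes held fixed
cfg <- run_config(n_simulations_1d = 100, n_permutations = 200,
                  prototype_size = 20, seed = 3)
aggregation_curve(verb, "visual", max_k = 5, cfg)[, 1:4]
#>   k  mean ci_low ci_high
#> 1 1 0.948  0.925   0.968
#> 2 2 1.000  0.999   1.000
#> 3 3 1.000  1.000   1.000
#> 4 4 1.000  1.000   1.000
#> 5 5 1.000  1.000   1.000
```

The t statistic has `n1 + n2 - 2` degrees of freedom (pooled variance).
The report line says the true mapping's rank agreement (rho = 0.52) beat
all 1,000 misaligned mappings. The curve's mean relative alignment rises
with exemplar count `k` and converges to 1.0; `ci_low`/`ci_high` are
percentile-bootstrap 95% bounds over simulations.

A thin command-line front end over the same functions lives at
`inst/cli/lexalign.R` with subcommands `metrics`, `align`, `aggregate`,
`simulate`, and `aoa`.

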