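#' Aggregate exemplars into a prototype
#'
#' A prototype is the arithmetic mean of `k` exemplars sampled uniformly
#' without replacement — the representation a learner forms after `k`
#' encounters with a category. `k = 1` returns a single exemplar verbatim;
#' `k` equal to the full exemplar count returns the category centroid.
#'
#' @param exemplars Numeric matrix, exemplars as rows.
#' @param k Number of exemplars to average, `1 <= k <= nrow(exemplars)`.
#' @param seed Optional integer seed for the draw.
#' @return Numeric vector of length `d`.
#' @export
aggregate_prototype <- function(exemplars, k, seed = NULL) {
  if (is.null(dim(exemplars))) exemplars <- matrix(exemplars, nrow = 1L)
  n <- nrow(exemplars)
  if (k < 1L || k > n) {
    stop("k = ", k, " out of range: category has ", n, " exemplars")
  }
  if (!is.null(seed)) set.seed(seed)
  colMeans(exemplars[sample.int(n, k), , drop = FALSE])
}

#' Percentile bootstrap confidence interval for a mean
#'
#' Resamples the values with replacement, recomputes the mean, and returns
#' the percentile interval of the resampled means.
#'
#' @param values Numeric vector (length >= 2).
#' @param level Confidence level in (0, 1).
#' @param n_resamples Number of bootstrap resamples.
#' @param seed Optional integer seed.
#' @return Numeric vector `c(lower, upper)`.
#' @export
bootstrap_ci <- function(values, level = 0.95, n_resamples = 1000L,
                         seed = NULL) {
  n <- length(values)
  if (n < 2L) stop("bootstrap_ci needs at least 2 values")
  if (!(level > 0 && level < 1)) stop("level must be in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  means <- vapply(seq_len(n_resamples), function(i) {
    mean(values[sample.int(n, n, replace = TRUE)])
  }, numeric(1))
  alpha <- (1 - level) / 2
  unname(stats::quantile(means, c(alpha, 1 - alpha), type = 7))
}

# One relative-alignment evaluation between a representative matrix pair.
relative_alignment_of <- function(rep_v, rep_l, n_permutations) {
  s_v <- cosine_similarity_matrix(rep_v)
  s_l <- cosine_similarity_matrix(rep_l)
  true <- alignment_strength(s_v, s_l)
  ps <- permuted_strengths(s_v, s_l,
                           sample_permutations(nrow(s_v), n_permutations))
  relative_alignment_strength(true, ps)
}

sample_prototype_matrix <- function(system, k) {
  t(vapply(system$exemplars, function(x) {
    colMeans(x[sample.int(nrow(x), k), , drop = FALSE])
  }, numeric(system$d)))
}

#' Incremental exemplar-aggregation curve
#'
#' Simulates a learner who accumulates exemplars in one modality while the
#' other modality's prototypes are already well formed. Per simulation, each
#' word of the aggregated modality receives a random exemplar order (without
#' replacement) and the fixed modality's prototype is formed from
#' `prototype_size` freshly sampled exemplars; for `k = 1..max_k` the first
#' `k` exemplars' mean represents each category (nested, so within a
#' simulation the information grows monotonically) and the relative alignment
#' strength of the true mapping is evaluated against `n_permutations`
#' misaligned mappings. Simulation means per `k` are reported with percentile
#' bootstrap confidence intervals.
#'
#' @param bimodal A `bimodal_system`.
#' @param aggregated_modality `"visual"` or `"linguistic"`: the modality whose
#'   exemplars accumulate; the other modality is held at its prototype.
#' @param max_k Largest exemplar count on the curve.
#' @param config A [run_config()]; uses `n_simulations_1d`, `n_permutations`,
#'   `prototype_size`, `ci_level`, `n_bootstrap` and the seed substream.
#' @return An object of class `aggregation_curve`: data.frame with columns
#'   `k`, `mean`, `ci_low`, `ci_high`, `n_simulations`, plus attribute
#'   `aggregated_modality`.
#' @export
aggregation_curve <- function(bimodal,
                              aggregated_modality = c("visual", "linguistic"),
                              max_k, config = run_config()) {
  stopifnot(inherits(bimodal, "bimodal_system"))
  aggregated_modality <- match.arg(aggregated_modality)
  agg <- bimodal[[aggregated_modality]]
  fixed <- bimodal[[setdiff(c("visual", "linguistic"), aggregated_modality)]]
  if (any(exemplar_counts(agg) < max_k)) {
    stop("aggregated modality needs >= ", max_k, " exemplars per word")
  }
  if (any(exemplar_counts(fixed) < config$prototype_size)) {
    stop("fixed modality needs >= ", config$prototype_size,
         " exemplars per word to form prototypes")
  }
  set.seed(derive_seed(config$seed, paste0("curve_", aggregated_modality)))
  n_sim <- config$n_simulations_1d
  rel <- matrix(NA_real_, nrow = n_sim, ncol = max_k)
  for (s in seq_len(n_sim)) {
    proto_fixed <- sample_prototype_matrix(fixed, config$prototype_size)
    # nested exemplar order per word: running sums give the k-prototype cheaply
    cums <- lapply(agg$exemplars, function(x) {
      ord <- sample.int(nrow(x), max_k)
      apply(x[ord, , drop = FALSE], 2, cumsum)
    })
    for (k in seq_len(max_k)) {
      proto_agg <- t(vapply(cums, function(cm) cm[k, ] / k, numeric(agg$d)))
      rel[s, k] <- if (aggregated_modality == "visual") {
        relative_alignment_of(proto_agg, proto_fixed, config$n_permutations)
      } else {
        relative_alignment_of(proto_fixed, proto_agg, config$n_permutations)
      }
    }
  }
  ci <- vapply(seq_len(max_k), function(k) {
    bootstrap_ci(rel[, k], level = config$ci_level,
                 n_resamples = config$n_bootstrap)
  }, numeric(2))
  out <- data.frame(k = seq_len(max_k),
                    mean = colMeans(rel),
                    ci_low = ci[1, ],
                    ci_high = ci[2, ],
                    n_simulations = n_sim)
  attr(out, "aggregated_modality") <- aggregated_modality
  class(out) <- c("aggregation_curve", "data.frame")
  out
}

#' Two-dimensional exemplar-aggregation grid
#'
#' Mean relative alignment strength as a function of the number of visual and
#' linguistic exemplars aggregated per category. Each cell is an independent
#' Monte Carlo estimate: per simulation, both modalities' prototypes are
#' formed by [aggregate_prototype()] from freshly sampled exemplars.
#'
#' @param bimodal A `bimodal_system`.
#' @param k_visual,k_linguistic Integer vectors of exemplar counts; the grid
#'   covers their Cartesian product.
#' @param config A [run_config()]; uses `n_simulations_2d`, `n_permutations`
#'   and the seed substream.
#' @return An object of class `aggregation_grid`: matrix of mean relative
#'   alignment strengths with rows indexed by `k_visual` and columns by
#'   `k_linguistic`, and attribute `n_simulations`.
#' @export
aggregation_grid <- function(bimodal, k_visual, k_linguistic,
                             config = run_config()) {
  stopifnot(inherits(bimodal, "bimodal_system"))
  if (any(exemplar_counts(bimodal$visual) < max(k_visual)) ||
      any(exemplar_counts(bimodal$linguistic) < max(k_linguistic))) {
    stop("exemplar availability below the requested grid maxima")
  }
  set.seed(derive_seed(config$seed, "grid"))
  n_sim <- config$n_simulations_2d
  out <- matrix(NA_real_, nrow = length(k_visual), ncol = length(k_linguistic),
                dimnames = list(k_visual = as.character(k_visual),
                                k_linguistic = as.character(k_linguistic)))
  for (i in seq_along(k_visual)) {
    for (j in seq_along(k_linguistic)) {
      vals <- vapply(seq_len(n_sim), function(s) {
        relative_alignment_of(
          sample_prototype_matrix(bimodal$visual, k_visual[i]),
          sample_prototype_matrix(bimodal$linguistic, k_linguistic[j]),
          config$n_permutations)
      }, numeric(1))
      out[i, j] <- mean(vals)
    }
  }
  attr(out, "n_simulations") <- n_sim
  class(out) <- c("aggregation_grid", class(out))
  out
}
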