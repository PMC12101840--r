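#' Cosine similarity matrix of category representatives
#'
#' Pairwise cosine similarity between one representative vector per word
#' (an exemplar, a sampled prototype, or the category centroid). The matrix is
#' symmetric with unit diagonal and entries in [-1, 1].
#'
#' @param representatives `N x d` numeric matrix, one representative per row
#'   (`N >= 3`: with two words the upper triangle has a single entry on which
#'   a rank correlation is undefined).
#' @return `N x N` similarity matrix carrying the rownames of the input.
#' @export
cosine_similarity_matrix <- function(representatives) {
  if (is.null(dim(representatives))) {
    stop("`representatives` must be a matrix with one vector per row")
  }
  n <- nrow(representatives)
  if (n < 3L) stop("need at least 3 representatives, got ", n)
  if (!all(is.finite(representatives))) stop("non-finite representative values")
  norms <- sqrt(rowSums(representatives^2))
  if (any(norms == 0)) {
    stop("zero-norm representative at row ", which(norms == 0)[1],
         ": cosine similarity undefined")
  }
  s <- tcrossprod(representatives / norms)
  s <- pmin(pmax(s, -1), 1)
  diag(s) <- 1
  dimnames(s) <- list(rownames(representatives), rownames(representatives))
  s
}

#' Strictly-upper-triangle entries of a similarity matrix
#'
#' Column-major order of the `N(N-1)/2` off-diagonal pairs; the fixed order is
#' what alignment statistics correlate over.
#'
#' @param s Square numeric matrix.
#' @return Numeric vector.
#' @export
upper_triangle <- function(s) {
  s[upper.tri(s)]
}

check_conformable <- function(s_v, s_l) {
  if (!is.matrix(s_v) || !is.matrix(s_l) || nrow(s_v) != ncol(s_v) ||
      nrow(s_l) != ncol(s_l)) {
    stop("similarity matrices must be square")
  }
  if (nrow(s_v) != nrow(s_l)) {
    stop("similarity matrices have different sizes: ", nrow(s_v), " vs ",
         nrow(s_l))
  }
  if (nrow(s_v) < 3L) stop("alignment needs at least 3 words")
  invisible(NULL)
}

#' Cross-modal alignment strength
#'
#' Spearman's rank correlation between the strictly-upper-triangle entries of
#' the visual and linguistic similarity matrices: a second-order (RSA-style)
#' statistic asking whether words that are similar in one modality are similar
#' in the other. Ties receive average ranks.
#'
#' If either upper triangle is constant the rank correlation is undefined; the
#' function then returns `NA` with a warning of class
#' `lexalign_undefined_alignment` rather than a silent value.
#'
#' @param s_v,s_l Similarity matrices over the same word order (`N >= 3`).
#' @return Spearman rho in [-1, 1], or `NA`.
#' @export
alignment_strength <- function(s_v, s_l) {
  check_conformable(s_v, s_l)
  x <- upper_triangle(s_v)
  y <- upper_triangle(s_l)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning(structure(
      class = c("lexalign_undefined_alignment", "warning", "condition"),
      list(message = "constant upper triangle: alignment strength undefined",
           call = sys.call())))
    return(NA_real_)
  }
  stats::cor(x, y, method = "spearman")
}

#' Per-word alignment profile
#'
#' For each word `i`, the Spearman correlation between row `i` of the visual
#' similarity matrix and row `i` of the linguistic one, with the diagonal
#' entry removed: how consistently word `i` relates to the other words across
#' modalities. This per-word decomposition is this package's own construction
#' (the system-level statistic does not define one) and is labelled as such in
#' pipeline outputs; it supplies the `alignment` feature of the learnability
#' table.
#'
#' @inheritParams alignment_strength
#' @return Named numeric vector of per-word Spearman rho values.
#' @export
word_alignment_profile <- function(s_v, s_l) {
  check_conformable(s_v, s_l)
  n <- nrow(s_v)
  out <- vapply(seq_len(n), function(i) {
    stats::cor(s_v[i, -i], s_l[i, -i], method = "spearman")
  }, numeric(1))
  names(out) <- rownames(s_v)
  out
}

#' Sample misaligned word mappings
#'
#' Draws permutations of `1..n_words` uniformly from all permutations except
#' the identity (fixed points are allowed, so these are not derangements),
#' independently and with replacement across draws. Each permutation is a
#' candidate wrong word-to-word mapping between the modalities.
#'
#' @param n_words Number of words (`>= 2`).
#' @param n_permutations Number of draws.
#' @param seed Optional integer seed for this draw.
#' @return Integer matrix, one permutation per row.
#' @export
sample_permutations <- function(n_words, n_permutations, seed = NULL) {
  if (n_words < 2L) stop("need at least 2 words to misalign")
  if (!is.null(seed)) set.seed(seed)
  idx <- seq_len(n_words)
  out <- matrix(0L, nrow = n_permutations, ncol = n_words)
  for (i in seq_len(n_permutations)) {
    repeat {
      p <- sample.int(n_words)
      if (!identical(p, idx)) break
    }
    out[i, ] <- p
  }
  out
}

#' Alignment strengths of permuted mappings
#'
#' For each permutation `p`, the alignment strength of the misaligned system
#' in which visual word `p[i]` stands for linguistic word `i`. Because cosine
#' similarity depends only on the vectors, this is computed by reindexing the
#' precomputed visual similarity matrix (`s_v[p, p]`) rather than recomputing
#' cosines — mathematically identical and O(N^2) per permutation.
#'
#' @inheritParams alignment_strength
#' @param permutations Integer matrix from [sample_permutations()], one
#'   permutation per row.
#' @return Numeric vector of alignment strengths, one per permutation.
#' @export
permuted_strengths <- function(s_v, s_l, permutations) {
  check_conformable(s_v, s_l)
  n <- nrow(s_v)
  if (!is.matrix(permutations)) permutations <- matrix(permutations, nrow = 1L)
  if (ncol(permutations) != n) {
    stop("permutations have ", ncol(permutations), " entries but the system has ",
         n, " words")
  }
  ut <- upper.tri(s_v)
  y <- s_l[ut]
  ry <- rank(y)
  ry <- ry - mean(ry)
  deny <- sqrt(sum(ry^2))
  vapply(seq_len(nrow(permutations)), function(k) {
    p <- permutations[k, ]
    if (anyDuplicated(p) || any(p < 1L) || any(p > n)) {
      stop("row ", k, " is not a permutation of 1..", n)
    }
    x <- s_v[p, p][ut]
    rx <- rank(x)
    rx <- rx - mean(rx)
    denx <- sqrt(sum(rx^2))
    if (denx == 0 || deny == 0) return(NA_real_)
    sum(rx * ry) / (denx * deny)  # Pearson on average ranks == Spearman
  }, numeric(1))
}

#' Relative alignment strength
#'
#' The fraction of permuted (misaligned) mappings whose alignment strength is
#' strictly lower than the true mapping's: a permutation-percentile statistic
#' in [0, 1]. Ties count as not lower, which is conservative for the true
#' mapping.
#'
#' @param true_strength Alignment strength of the true mapping.
#' @param permuted Numeric vector of permuted-mapping strengths (length >= 1).
#' @return Fraction in [0, 1].
#' @export
relative_alignment_strength <- function(true_strength, permuted) {
  if (length(permuted) < 1L) stop("empty permuted sample")
  if (!is.finite(true_strength)) stop("true alignment strength is not finite")
  if (anyNA(permuted)) stop("NA in permuted strengths")
  mean(permuted < true_strength)
}

#' Full alignment report for a pair of similarity matrices
#'
#' Computes the true alignment strength, a sample of permuted-mapping
#' strengths, and the relative alignment strength in one call.
#'
#' @inheritParams alignment_strength
#' @param n_permutations Number of misaligned mappings to sample.
#' @param seed Optional integer seed.
#' @return An object of class `alignment_report`: list with `true_strength`,
#'   `permuted_strengths`, `relative_strength`, `n_permutations`.
#' @export
alignment_report <- function(s_v, s_l, n_permutations = 1000L, seed = NULL) {
  check_conformable(s_v, s_l)
  true <- alignment_strength(s_v, s_l)
  perms <- sample_permutations(nrow(s_v), n_permutations, seed = seed)
  ps <- permuted_strengths(s_v, s_l, perms)
  structure(
    list(true_strength = true,
         permuted_strengths = ps,
         relative_strength = relative_alignment_strength(true, ps),
         n_permutations = as.integer(n_permutations)),
    class = "alignment_report"
  )
}

#' @export
print.alignment_report <- function(x, ...) {
  cat(sprintf(paste0("Alignment strength rho = %.4f; relative alignment ",
                     "strength = %.3f (%d permutations)\n"),
              x$true_strength, x$relative_strength, x$n_permutations))
  invisible(x)
}

#' Alignment of single-exemplar systems
#'
#' Models a learner who has seen exactly one instance per category: draws
#' `n_systems` systems, each built from one uniformly sampled exemplar per
#' word per modality, and records each system's true alignment strength and
#' its permuted-mapping strengths. The pooled true and permuted samples are
#' compared with the pooled-variance t-test (degrees of freedom
#' `n_systems + n_systems * n_permutations - 2`).
#'
#' @param bimodal A `bimodal_system`.
#' @param n_systems Number of sampled single-exemplar systems.
#' @param config A [run_config()]; supplies `n_permutations` and the seed
#'   substream.
#' @return List with `true_strengths`, `permuted_strengths` (pooled),
#'   `relative_strengths` (per system), and `comparison`
#'   (a `group_comparison`).
#' @export
single_exemplar_analysis <- function(bimodal, n_systems,
                                     config = run_config()) {
  stopifnot(inherits(bimodal, "bimodal_system"))
  set.seed(derive_seed(config$seed, "single_exemplar"))
  n_perm <- config$n_permutations
  true_s <- numeric(n_systems)
  rel_s <- numeric(n_systems)
  perm_s <- vector("list", n_systems)
  for (s in seq_len(n_systems)) {
    vis <- t(vapply(bimodal$visual$exemplars, function(x) {
      x[sample.int(nrow(x), 1L), ]
    }, numeric(bimodal$visual$d)))
    lin <- t(vapply(bimodal$linguistic$exemplars, function(x) {
      x[sample.int(nrow(x), 1L), ]
    }, numeric(bimodal$linguistic$d)))
    s_v <- cosine_similarity_matrix(vis)
    s_l <- cosine_similarity_matrix(lin)
    true_s[s] <- alignment_strength(s_v, s_l)
    ps <- permuted_strengths(s_v, s_l, sample_permutations(nrow(s_v), n_perm))
    perm_s[[s]] <- ps
    rel_s[s] <- relative_alignment_strength(true_s[s], ps)
  }
  pooled <- unlist(perm_s, use.names = FALSE)
  list(true_strengths = true_s,
       permuted_strengths = pooled,
       relative_strengths = rel_s,
       comparison = compare_groups(true_s, pooled))
}
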