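#' Category centroid
#'
#' Coordinate-wise arithmetic mean of a category's exemplar vectors.
#'
#' @param exemplars Numeric matrix with exemplars as rows (or a single
#'   vector).
#' @return Numeric vector of length `d`.
#' @export
category_centroid <- function(exemplars) {
  if (is.null(dim(exemplars))) exemplars <- matrix(exemplars, nrow = 1L)
  if (nrow(exemplars) < 1L) stop("cannot take the centroid of no exemplars")
  colMeans(exemplars)
}

#' Centroids of every category in a system
#'
#' @param system An `embedding_system`.
#' @return `N x d` matrix, one centroid per row, rownames = words.
#' @export
system_centroids <- function(system) {
  stopifnot(inherits(system, "embedding_system"))
  out <- t(vapply(system$exemplars, category_centroid, numeric(system$d)))
  rownames(out) <- system$words
  out
}

#' Within-category variability
#'
#' The variability of a category is the mean Euclidean distance from its
#' exemplars to the category centroid: a diffuse category (exemplars spread
#' widely around the prototype) has high variability, a tight one has
#' variability near zero.
#'
#' @param system An `embedding_system`.
#' @return Named numeric vector, one nonnegative value per word.
#' @export
variability <- function(system) {
  stopifnot(inherits(system, "embedding_system"))
  out <- vapply(system$exemplars, function(x) {
    ctr <- colMeans(x)
    mean(sqrt(rowSums(sweep(x, 2, ctr)^2)))
  }, numeric(1))
  names(out) <- system$words
  out
}

#' Between-category discriminability
#'
#' The discriminability of category `i` is the mean Euclidean distance from
#' the exemplars of all *other* categories to centroid `i`: a category whose
#' centroid sits far from everything else is easy to tell apart (high
#' discriminability); overlapping categories score low. Each other category
#' contributes its own mean distance, and those `N - 1` means are averaged,
#' so categories are weighted equally even when exemplar counts differ (with
#' equal counts this is the plain grand mean over the `(N-1) * K` exemplars).
#'
#' @param system An `embedding_system` with at least 2 words.
#' @return Named numeric vector, one nonnegative value per word.
#' @export
discriminability <- function(system) {
  stopifnot(inherits(system, "embedding_system"))
  n <- length(system$words)
  if (n < 2L) stop("discriminability needs at least 2 categories")
  centroids <- system_centroids(system)
  # mean distance from category j's exemplars to every centroid: N x N matrix
  mean_dist <- t(vapply(system$exemplars, function(x) {
    # distances of each exemplar of j to all centroids at once
    d2 <- outer(rowSums(x^2), rowSums(centroids^2), "+") -
      2 * tcrossprod(x, centroids)
    colMeans(sqrt(pmax(d2, 0)))
  }, numeric(n)))
  out <- vapply(seq_len(n), function(i) mean(mean_dist[-i, i]), numeric(1))
  names(out) <- system$words
  out
}

#' Category-structure metrics of a bimodal system
#'
#' Convenience wrapper returning all four per-word metrics plus centroids.
#'
#' @param bimodal A `bimodal_system`.
#' @return A list with `table` (data.frame: word, linguistic_variability,
#'   visual_variability, linguistic_discriminability,
#'   visual_discriminability) and `centroids` (list of the two centroid
#'   matrices).
#' @export
category_structure <- function(bimodal) {
  stopifnot(inherits(bimodal, "bimodal_system"))
  tab <- data.frame(
    word = bimodal$words,
    linguistic_variability = unname(variability(bimodal$linguistic)),
    visual_variability = unname(variability(bimodal$visual)),
    linguistic_discriminability = unname(discriminability(bimodal$linguistic)),
    visual_discriminability = unname(discriminability(bimodal$visual)),
    stringsAsFactors = FALSE
  )
  list(table = tab,
       centroids = list(linguistic = system_centroids(bimodal$linguistic),
                        visual = system_centroids(bimodal$visual)))
}

#' Pooled-variance two-sample comparison
#'
#' Student's two-sample t-test with pooled variance (degrees of freedom
#' `n1 + n2 - 2`), two-sided. Used for noun-versus-verb comparisons of the
#' per-word metrics and for the true-versus-permuted alignment comparison.
#'
#' @param values_a,values_b Numeric vectors, each of length >= 2.
#' @return An object of class `group_comparison`: list with `t_statistic`,
#'   `degrees_of_freedom`, `p_value`, `group_means`.
#' @export
compare_groups <- function(values_a, values_b) {
  n1 <- length(values_a); n2 <- length(values_b)
  if (n1 < 2L || n2 < 2L) stop("each group needs at least 2 values")
  m1 <- mean(values_a); m2 <- mean(values_b)
  df <- n1 + n2 - 2L
  sp2 <- ((n1 - 1) * stats::var(values_a) + (n2 - 1) * stats::var(values_b)) / df
  if (sp2 == 0) {
    if (m1 == m2) {
      res <- list(t_statistic = 0, degrees_of_freedom = df, p_value = 1,
                  group_means = c(m1, m2))
      return(structure(res, class = "group_comparison"))
    }
    stop("zero pooled variance with unequal means: t statistic undefined")
  }
  tt <- stats::t.test(values_a, values_b, var.equal = TRUE)
  structure(
    list(t_statistic = unname(tt$statistic),
         degrees_of_freedom = as.integer(unname(tt$parameter)),
         p_value = tt$p.value,
         group_means = c(m1, m2)),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("t(%d) = %.3f, p = %.3g; means %.4g vs %.4g\n",
              x$degrees_of_freedom, x$t_statistic, x$p_value,
              x$group_means[1], x$group_means[2]))
  invisible(x)
}
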