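# Independent brute-force oracles: plain loops, no shared code with the
# package implementations they check.

oracle_euclid <- function(a, b) sqrt(sum((a - b)^2))

oracle_centroid <- function(x) {
  out <- numeric(ncol(x))
  for (j in seq_len(ncol(x))) {
    s <- 0
    for (i in seq_len(nrow(x))) s <- s + x[i, j]
    out[j] <- s / nrow(x)
  }
  out
}

oracle_variability <- function(system) {
  vapply(system$exemplars, function(x) {
    ctr <- oracle_centroid(x)
    total <- 0
    for (i in seq_len(nrow(x))) total <- total + oracle_euclid(x[i, ], ctr)
    total / nrow(x)
  }, numeric(1))
}

oracle_discriminability <- function(system) {
  n <- length(system$words)
  out <- numeric(n)
  for (i in seq_len(n)) {
    ctr <- oracle_centroid(system$exemplars[[i]])
    acc <- 0
    for (j in seq_len(n)) {
      if (j == i) next
      xj <- system$exemplars[[j]]
      cat_mean <- 0
      for (k in seq_len(nrow(xj))) {
        cat_mean <- cat_mean + oracle_euclid(xj[k, ], ctr)
      }
      acc <- acc + cat_mean / nrow(xj)
    }
    out[i] <- acc / (n - 1)
  }
  out
}

oracle_cosine_matrix <- function(reps) {
  n <- nrow(reps)
  s <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      s[i, j] <- sum(reps[i, ] * reps[j, ]) /
        (sqrt(sum(reps[i, ]^2)) * sqrt(sum(reps[j, ]^2)))
    }
  }
  s
}

# average ranks by explicit counting, then the Pearson sum formula
oracle_rank <- function(x) {
  n <- length(x)
  r <- numeric(n)
  for (i in seq_len(n)) {
    less <- 0; equal <- 0
    for (j in seq_len(n)) {
      if (x[j] < x[i]) less <- less + 1
      if (x[j] == x[i]) equal <- equal + 1
    }
    r[i] <- less + (equal + 1) / 2
  }
  r
}

oracle_spearman <- function(x, y) {
  rx <- oracle_rank(x); ry <- oracle_rank(y)
  mx <- mean(rx); my <- mean(ry)
  num <- sum((rx - mx) * (ry - my))
  num / sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

oracle_alignment_strength <- function(s_v, s_l) {
  oracle_spearman(s_v[upper.tri(s_v)], s_l[upper.tri(s_l)])
}

random_system <- function(n_words, d, counts, modality = "visual",
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length(counts) == 1L) counts <- rep(counts, n_words)
  words <- paste0("w", seq_len(n_words))
  exemplars <- lapply(counts, function(k) matrix(rnorm(k * d) + 2, nrow = k))
  embedding_system(words, exemplars, modality = modality)
}
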