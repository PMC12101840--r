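make_sim <- function(reps) cosine_similarity_matrix(reps)

test_that("cosine similarity matrices match the definitional loop", {
  s <- cosine_similarity_matrix(diag(3))
  expect_equal(s, diag(3), ignore_attr = TRUE)

  v <- c(1, 2, 3)
  reps <- rbind(v, 2 * v, c(0, 0, 1))
  s2 <- cosine_similarity_matrix(reps)
  expect_equal(s2[1, 2], 1)

  set.seed(14)
  reps4 <- matrix(rnorm(4 * 6), nrow = 4)
  expect_equal(cosine_similarity_matrix(reps4), oracle_cosine_matrix(reps4),
               tolerance = 1e-12, ignore_attr = TRUE)

  expect_error(cosine_similarity_matrix(rbind(c(1, 0), c(0, 1))), "at least 3")
  expect_error(cosine_similarity_matrix(rbind(c(1, 0), c(0, 0), c(0, 1))),
               "zero-norm")
})

test_that("alignment strength is the Spearman rho of the upper triangles", {
  set.seed(2)
  reps <- matrix(rnorm(5 * 4), nrow = 5)
  s <- make_sim(reps)
  expect_equal(alignment_strength(s, s), 1)

  # reversed rank order of the upper triangle entries
  s_rev <- s
  s_rev[upper.tri(s_rev)] <- -rank(s[upper.tri(s)])
  s_rev[lower.tri(s_rev)] <- t(s_rev)[lower.tri(s_rev)]
  expect_equal(alignment_strength(s_rev, s), -1)

  # textbook rank-difference value for one swapped pair among 6 entries
  tri_a <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6)
  tri_b <- c(0.1, 0.2, 0.3, 0.4, 0.6, 0.5)
  mk <- function(tri) {
    m <- diag(4)
    m[upper.tri(m)] <- tri
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    m
  }
  expect_equal(alignment_strength(mk(tri_a), mk(tri_b)),
               1 - 6 * 2 / (6 * 35), tolerance = 1e-12)
  expect_equal(alignment_strength(mk(tri_a), mk(tri_b)), 0.9429,
               tolerance = 1e-4)

  set.seed(3)
  s2 <- make_sim(matrix(rnorm(5 * 4), nrow = 5))
  expect_equal(alignment_strength(s, s2), oracle_alignment_strength(s, s2),
               tolerance = 1e-12)
})

test_that("a constant upper triangle yields a flagged undefined result", {
  flat <- matrix(0.5, 4, 4); diag(flat) <- 1
  set.seed(2)
  s <- make_sim(matrix(rnorm(4 * 3), nrow = 4))
  expect_warning(out <- alignment_strength(flat, s),
                 class = "lexalign_undefined_alignment")
  expect_true(is.na(out))
})

test_that("alignment strength is invariant to increasing transforms", {
  set.seed(9)
  s_v <- make_sim(matrix(rnorm(6 * 5), nrow = 6))
  s_l <- make_sim(matrix(rnorm(6 * 5), nrow = 6))
  base <- alignment_strength(s_v, s_l)
  for (g in list(function(x) x^3, function(x) exp(2 * x),
                 function(x) atan(x))) {
    expect_equal(alignment_strength(g(s_v), s_l), base, tolerance = 1e-12)
    expect_equal(alignment_strength(s_v, g(s_l)), base, tolerance = 1e-12)
  }
})

test_that("per-word alignment profiles detect a misaligned word", {
  set.seed(4)
  s <- make_sim(matrix(rnorm(8 * 6), nrow = 8))
  expect_equal(unname(word_alignment_profile(s, s)), rep(1, 8))

  # shuffling one word's visual row should single that word out
  set.seed(41)
  reps_v <- matrix(rnorm(10 * 6), nrow = 10)
  bad <- reps_v
  bad[3, ] <- rnorm(6)
  prof <- word_alignment_profile(make_sim(bad), make_sim(reps_v))
  expect_equal(which.min(prof), 3L, ignore_attr = TRUE)
})

test_that("per-word profiles are centered near zero for independent modalities", {
  set.seed(77)
  means <- replicate(50, {
    s_v <- make_sim(matrix(rnorm(40 * 8), nrow = 40))
    s_l <- make_sim(matrix(rnorm(40 * 8), nrow = 40))
    mean(word_alignment_profile(s_v, s_l))
  })
  expect_lt(abs(mean(means)), 0.1)
})

test_that("permutations are uniform over non-identity mappings", {
  p2 <- sample_permutations(2, 25, seed = 1)
  expect_true(all(apply(p2, 1, identical, y = c(2L, 1L))))

  for (s in 1:5) {
    pn <- sample_permutations(4, 200, seed = s)
    expect_false(any(apply(pn, 1, identical, y = 1:4)))
  }

  # N = 3: the 5 non-identity permutations should be equally frequent
  draws <- sample_permutations(3, 20000, seed = 99)
  key <- apply(draws, 1, paste, collapse = "")
  counts <- table(key)
  expect_identical(length(counts), 5L)
  gof <- chisq.test(counts, p = rep(1 / 5, 5))
  expect_gt(gof$p.value, 0.001)

  expect_error(sample_permutations(1, 5), "at least 2")
})

test_that("permuted strengths equal recomputation from permuted pairings", {
  set.seed(6)
  vis <- matrix(rnorm(6 * 5), nrow = 6)
  lin <- matrix(rnorm(6 * 4), nrow = 6)
  s_v <- make_sim(vis); s_l <- make_sim(lin)

  # identity permutation reproduces the true strength exactly
  expect_equal(permuted_strengths(s_v, s_l, matrix(1:6, nrow = 1)),
               alignment_strength(s_v, s_l), tolerance = 1e-12)

  perms <- sample_permutations(6, 20, seed = 3)
  fast <- permuted_strengths(s_v, s_l, perms)
  slow <- apply(perms, 1, function(p) {
    alignment_strength(make_sim(vis[p, , drop = FALSE]), s_l)
  })
  expect_equal(fast, slow, tolerance = 1e-12)

  # relabeling both modalities jointly is a no-op
  p <- perms[1, ]
  expect_equal(alignment_strength(s_v[p, p], s_l[p, p]),
               alignment_strength(s_v, s_l), tolerance = 1e-12)

  expect_error(permuted_strengths(s_v, s_l, matrix(rep(1L, 6), nrow = 1)),
               "not a permutation")
})

test_that("relative alignment strength counts strictly lower permuted values", {
  expect_equal(relative_alignment_strength(0.9, rep(0.5, 1000)), 1)
  expect_equal(relative_alignment_strength(0.5, c(0.1, 0.2, 0.6, 0.7)), 0.5)
  expect_equal(relative_alignment_strength(0.4, rep(0.4, 10)), 0)
  expect_error(relative_alignment_strength(0.4, numeric(0)), "empty")
  expect_error(relative_alignment_strength(NA_real_, c(0.1)), "finite")
})

test_that("alignment reports are reproducible under a fixed seed", {
  set.seed(8)
  s_v <- make_sim(matrix(rnorm(10 * 6), nrow = 10))
  s_l <- make_sim(matrix(rnorm(10 * 6), nrow = 10))
  r1 <- alignment_report(s_v, s_l, n_permutations = 100, seed = 5)
  r2 <- alignment_report(s_v, s_l, n_permutations = 100, seed = 5)
  expect_identical(r1, r2)
  expect_equal(r1$relative_strength,
               relative_alignment_strength(r1$true_strength,
                                           r1$permuted_strengths))
})

test_that("single-exemplar systems are calibrated on independent modalities", {
  params <- synthetic_system_params(n_words = 15, alignment = 0,
                                    n_exemplars_visual = 4,
                                    n_exemplars_linguistic = 4, seed = 12)
  bimodal <- generate_bimodal_system(params)$system
  cfg <- run_config(n_permutations = 100, seed = 7)
  res <- single_exemplar_analysis(bimodal, n_systems = 100, cfg)
  expect_length(res$true_strengths, 100)
  expect_length(res$permuted_strengths, 100 * 100)
  expect_identical(res$comparison$degrees_of_freedom, 100L + 100L * 100L - 2L)
  # null: the true mapping is exchangeable with permuted ones
  expect_gt(mean(res$relative_strengths), 0.35)
  expect_lt(mean(res$relative_strengths), 0.65)
})

test_that("single-exemplar analysis hits 1.0 in the noiseless aligned limit", {
  params <- synthetic_system_params(n_words = 8, alignment = 1,
                                    dispersion_visual = 0,
                                    dispersion_linguistic = 0,
                                    n_exemplars_visual = 3,
                                    n_exemplars_linguistic = 3, seed = 2)
  bimodal <- generate_bimodal_system(params)$system
  res <- single_exemplar_analysis(bimodal, n_systems = 10,
                                  run_config(n_permutations = 50, seed = 3))
  expect_equal(res$true_strengths, rep(1, 10))
  expect_equal(res$relative_strengths, rep(1, 10))
})
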