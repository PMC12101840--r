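#' Random matrix with orthonormal columns
#'
#' Maps a latent space isometrically into a (possibly larger) modality space:
#' norms and angles — hence cosine similarities — of latent vectors are
#' preserved exactly, which gives the noiseless fully-aligned generator limit
#' an analytic anchor (identical similarity structure in both modalities).
#' Obtained from the QR decomposition of a Gaussian matrix with column signs
#' fixed for reproducibility.
#'
#' @param d_from Latent dimension (`<= d_to`).
#' @param d_to Target dimension.
#' @param seed Optional integer seed.
#' @return `d_to x d_from` matrix with orthonormal columns.
#' @export
random_orthonormal_map <- function(d_from, d_to, seed = NULL) {
  if (d_from > d_to) {
    stop("cannot embed dimension ", d_from, " isometrically into ", d_to)
  }
  if (!is.null(seed)) set.seed(seed)
  a <- matrix(stats::rnorm(d_to * d_from), nrow = d_to)
  qr_a <- qr(a)
  q <- qr.Q(qr_a)
  sign_fix <- sign(diag(qr.R(qr_a)))
  sign_fix[sign_fix == 0] <- 1
  sweep(q, 2, sign_fix, `*`)
}

#' Parameters of the synthetic bimodal-system generator
#'
#' The generator emulates the statistical structure the alignment analyses
#' consume: category-clustered embeddings in two modality spaces whose
#' category directions share a latent component. Per word `i` a latent
#' direction `z_i` is drawn standard normal in `d_latent` dimensions; each
#' modality's category direction mixes the shared latent with a
#' modality-specific one as
#' `u_i = sqrt(a) * M z_i + sqrt(1 - a) * M' e_i`
#' through orthonormal maps `M`, `M'`, so the direction's variance is constant
#' in `a` and the mixing weight isolates cross-modal alignment from category
#' separation. Exemplar `j` of word `i` is `s * u_i + sigma * eps_ij` with
#' isotropic Gaussian noise.
#'
#' @param n_words Number of word categories (`>= 3`).
#' @param d_latent Shared latent dimension (`<= min(d_visual, d_linguistic)`).
#' @param d_visual,d_linguistic Modality embedding dimensions.
#' @param alignment Mixing weight `a` in [0, 1]: 1 = fully shared category
#'   structure across modalities, 0 = independent modalities.
#' @param separation Between-category scale `s > 0` multiplying the category
#'   direction; larger values separate categories relative to the noise.
#' @param dispersion_visual,dispersion_linguistic Within-category noise
#'   standard deviations `sigma >= 0`.
#' @param n_exemplars_visual,n_exemplars_linguistic Exemplars per word.
#' @param seed Integer seed fixing every generated byte.
#' @return An object of class `synthetic_system_params`.
#' @export
synthetic_system_params <- function(n_words = 40L, d_latent = 16L,
                                    d_visual = 32L, d_linguistic = 32L,
                                    alignment = 0.8, separation = 1,
                                    dispersion_visual = 1,
                                    dispersion_linguistic = 1,
                                    n_exemplars_visual = 20L,
                                    n_exemplars_linguistic = 20L,
                                    seed = 1L) {
  if (n_words < 3L) stop("n_words must be >= 3")
  if (alignment < 0 || alignment > 1) stop("alignment must be in [0, 1]")
  if (separation <= 0) stop("separation must be > 0")
  if (dispersion_visual < 0 || dispersion_linguistic < 0) {
    stop("dispersions must be >= 0")
  }
  if (d_latent > min(d_visual, d_linguistic)) {
    stop("d_latent must not exceed either modality dimension")
  }
  structure(
    list(n_words = as.integer(n_words), d_latent = as.integer(d_latent),
         d_visual = as.integer(d_visual),
         d_linguistic = as.integer(d_linguistic),
         alignment = alignment, separation = separation,
         dispersion_visual = dispersion_visual,
         dispersion_linguistic = dispersion_linguistic,
         n_exemplars_visual = as.integer(n_exemplars_visual),
         n_exemplars_linguistic = as.integer(n_exemplars_linguistic),
         seed = as.integer(seed)),
    class = "synthetic_system_params"
  )
}

#' Generate a synthetic bimodal system with known ground truth
#'
#' @param params A [synthetic_system_params()].
#' @return List with `system` (a `bimodal_system`) and `ground_truth` (the
#'   parameters plus the latent word directions and per-modality category
#'   directions).
#' @seealso [synthetic_system_params()] for the generative model.
#' @export
generate_bimodal_system <- function(params = synthetic_system_params()) {
  stopifnot(inherits(params, "synthetic_system_params"))
  set.seed(params$seed)
  n <- params$n_words
  words <- sprintf("w%03d", seq_len(n))
  z <- matrix(stats::rnorm(n * params$d_latent), nrow = n)

  gen_modality <- function(d_mod, sigma, n_ex, modality) {
    m_shared <- random_orthonormal_map(params$d_latent, d_mod)
    m_specific <- random_orthonormal_map(params$d_latent, d_mod)
    e <- matrix(stats::rnorm(n * params$d_latent), nrow = n)
    u <- sqrt(params$alignment) * z %*% t(m_shared) +
      sqrt(1 - params$alignment) * e %*% t(m_specific)
    exemplars <- lapply(seq_len(n), function(i) {
      noise <- matrix(stats::rnorm(n_ex * d_mod, sd = sigma), nrow = n_ex)
      sweep(noise, 2, params$separation * u[i, ], `+`)
    })
    list(system = embedding_system(words, exemplars, modality = modality),
         directions = u)
  }

  vis <- gen_modality(params$d_visual, params$dispersion_visual,
                      params$n_exemplars_visual, "visual")
  lin <- gen_modality(params$d_linguistic, params$dispersion_linguistic,
                      params$n_exemplars_linguistic, "linguistic")
  list(
    system = pair_systems(lin$system, vis$system),
    ground_truth = list(params = params, latent = z,
                        directions_visual = vis$directions,
                        directions_linguistic = lin$directions)
  )
}

#' Noun-like and verb-like generator presets
#'
#' Two parameterizations contrasting the category structure of concrete nouns
#' and relational verbs: noun-like categories are visually tight and well
#' separated (low visual dispersion, high separation), verb-like categories
#' are visually diffuse and less separated (high visual dispersion, lower
#' separation). The cross-modal mixing weight and linguistic dispersion are
#' shared so the contrast isolates visual category structure.
#'
#' @param name `"noun_like"` or `"verb_like"`.
#' @param n_words Number of word categories.
#' @param seed Integer seed.
#' @return A [synthetic_system_params()].
#' @export
preset_params <- function(name = c("noun_like", "verb_like"), n_words = 40L,
                          seed = 1L) {
  name <- match.arg(name)
  if (name == "noun_like") {
    synthetic_system_params(n_words = n_words, alignment = 0.8,
                            separation = 1.5, dispersion_visual = 0.8,
                            dispersion_linguistic = 1.2, seed = seed)
  } else {
    synthetic_system_params(n_words = n_words, alignment = 0.8,
                            separation = 1.0, dispersion_visual = 2.0,
                            dispersion_linguistic = 1.2, seed = seed)
  }
}

#' Parameters of the synthetic learnability-table generator
#'
#' Effect sizes are in months per standard deviation of the (standardized)
#' feature, so `|effect|` is directly the feature's generative importance.
#' Defaults reflect the direction structure expected for early word learning:
#' frequent words are learned earlier, verbs and visually variable categories
#' later, well-aligned categories earlier.
#'
#' @param n_words Number of rows (word categories).
#' @param effects Named numeric vector of effect sizes (months per feature
#'   SD) for `log_frequency`, `word_type`, `visual_variability`,
#'   `linguistic_variability`, `alignment`, `visual_discriminability`,
#'   `linguistic_discriminability`.
#' @param noise_sd Residual standard deviation of age of acquisition, months.
#' @param include_noise_feature Append a pure-noise feature (zero generative
#'   effect) as a null reference for attribution checks.
#' @param intercept Baseline age of acquisition, months.
#' @param seed Integer seed.
#' @return An object of class `synthetic_learnability_params`.
#' @export
synthetic_learnability_params <- function(
    n_words = 400L,
    effects = c(log_frequency = -4, word_type = 3, visual_variability = 2.5,
                alignment = -1.5, linguistic_variability = 1,
                visual_discriminability = -0.5,
                linguistic_discriminability = 0.25),
    noise_sd = 1, include_noise_feature = TRUE, intercept = 22,
    seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  required <- c("log_frequency", "word_type", "visual_variability",
                "linguistic_variability", "alignment",
                "visual_discriminability", "linguistic_discriminability")
  missing <- setdiff(required, names(effects))
  if (length(missing)) stop("missing effect sizes: ",
                            paste(missing, collapse = ", "))
  structure(
    list(n_words = as.integer(n_words), effects = effects[required],
         noise_sd = noise_sd,
         include_noise_feature = isTRUE(include_noise_feature),
         intercept = intercept, seed = as.integer(seed)),
    class = "synthetic_learnability_params"
  )
}

#' Generate a synthetic learnability table with known ground truth
#'
#' Draws per-word features with realistic dependence — word type shifts the
#' variability and alignment distributions (verb categories more variable,
#' less aligned) — and composes age of acquisition as a linear combination of
#' the standardized features under the stated effect sizes plus Gaussian
#' noise, truncated below at 6 months.
#'
#' @param params A [synthetic_learnability_params()].
#' @return List with `table` (data.frame usable by [fit_aoa_model()]) and
#'   `ground_truth` (the parameters plus each feature's realized standard
#'   deviation and the noise-free ages).
#' @export
generate_learnability_table <- function(params = synthetic_learnability_params()) {
  stopifnot(inherits(params, "synthetic_learnability_params"))
  set.seed(params$seed)
  n <- params$n_words
  word_type <- stats::rbinom(n, 1, 0.5)  # 0 = noun, 1 = verb
  log_frequency <- stats::rnorm(n, mean = 3, sd = 1)
  feats <- data.frame(
    word_type = word_type,
    log_frequency = log_frequency,
    visual_variability = pmax(stats::rnorm(n, 10 + 4 * word_type, 2), 0.1),
    linguistic_variability = pmax(stats::rnorm(n, 8 + 2 * word_type, 2), 0.1),
    alignment = pmin(pmax(stats::rnorm(n, 0.35 - 0.15 * word_type, 0.1), -1), 1),
    visual_discriminability = pmax(stats::rnorm(n, 12, 2), 0.1),
    linguistic_discriminability = pmax(stats::rnorm(n, 12, 2), 0.1)
  )
  if (params$include_noise_feature) feats$noise_feature <- stats::rnorm(n)
  z <- scale(as.matrix(feats[names(params$effects)]))
  aoa_clean <- params$intercept + drop(z %*% params$effects)
  aoa <- pmax(aoa_clean + stats::rnorm(n, sd = params$noise_sd), 6)
  tab <- cbind(
    data.frame(word = sprintf("w%04d", seq_len(n)),
               stringsAsFactors = FALSE),
    feats,
    data.frame(frequency = 10^log_frequency, aoa_months = aoa)
  )
  list(table = tab,
       ground_truth = list(params = params,
                           feature_sd = attr(z, "scaled:scale"),
                           aoa_noise_free = aoa_clean))
}
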