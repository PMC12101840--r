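#' Construct an embedding system
#'
#' An embedding system holds, for an ordered set of `N` word categories in one
#' modality (linguistic or visual), the exemplar vectors of each category. All
#' exemplars share a common embedding dimension `d`; exemplar counts may differ
#' between words.
#'
#' @param words Character vector of `N >= 2` distinct word labels. The order is
#'   meaningful and is preserved by all downstream computations.
#' @param exemplars List of length `N`; element `i` is a numeric matrix whose
#'   rows are the exemplar vectors of word `i` (at least one row, `d` columns).
#'   A single vector is accepted and treated as a one-row matrix.
#' @param modality Either `"linguistic"` or `"visual"`.
#'
#' @return An object of class `embedding_system`: a list with elements
#'   `words`, `exemplars` (named list of matrices), `modality`, `d`.
#'
#' @details Vectors must be finite and non-degenerate: a zero-norm exemplar is
#'   rejected because cosine similarity is undefined for it.
#'
#' @examples
#' sys <- embedding_system(
#'   words = c("dog", "cat"),
#'   exemplars = list(rbind(c(1, 0), c(1, 1)), rbind(c(0, 1), c(1, 2))),
#'   modality = "visual"
#' )
#' sys$d
#' @export
embedding_system <- function(words, exemplars, modality = c("linguistic", "visual")) {
  modality <- match.arg(modality)
  words <- as.character(words)
  if (length(words) < 2L) {
    stop("an embedding system needs at least 2 words, got ", length(words))
  }
  if (anyDuplicated(words)) {
    stop("duplicated word labels: ",
         paste(unique(words[duplicated(words)]), collapse = ", "))
  }
  if (length(exemplars) != length(words)) {
    stop("`exemplars` must have one element per word (",
         length(words), "), got ", length(exemplars))
  }
  exemplars <- lapply(exemplars, function(x) {
    if (is.null(dim(x))) x <- matrix(as.numeric(x), nrow = 1L)
    storage.mode(x) <- "double"
    x
  })
  d <- unique(vapply(exemplars, ncol, integer(1)))
  if (length(d) != 1L) {
    stop("exemplar matrices disagree on embedding dimension: ",
         paste(sort(d), collapse = " vs "))
  }
  if (d < 1L) stop("embedding dimension must be >= 1")
  for (i in seq_along(words)) {
    x <- exemplars[[i]]
    if (nrow(x) < 1L) stop("word '", words[i], "' has no exemplars")
    if (!all(is.finite(x))) {
      stop("non-finite values in exemplars of word '", words[i], "'")
    }
    norms <- sqrt(rowSums(x^2))
    if (any(norms == 0)) {
      stop("zero-norm exemplar (row ", which(norms == 0)[1], ") for word '",
           words[i], "': cosine similarity is undefined")
    }
  }
  names(exemplars) <- words
  structure(
    list(words = words, exemplars = exemplars, modality = modality, d = d),
    class = "embedding_system"
  )
}

#' @export
print.embedding_system <- function(x, ...) {
  counts <- vapply(x$exemplars, nrow, integer(1))
  cat("Embedding system (", x$modality, "): ", length(x$words), " words, d = ",
      x$d, ", exemplars/word ", min(counts), "-", max(counts), "\n", sep = "")
  invisible(x)
}

#' Number of exemplars per word
#' @param system An `embedding_system`.
#' @return Named integer vector.
#' @export
exemplar_counts <- function(system) {
  stopifnot(inherits(system, "embedding_system"))
  vapply(system$exemplars, nrow, integer(1))
}

#' Pair a linguistic and a visual embedding system
#'
#' Combines the two modalities of one word set into a bimodal system under the
#' true word-to-word correspondence. The word sets must be identical; the
#' visual system is reordered to the linguistic system's word order, which is
#' the canonical order for all downstream indices.
#'
#' @param linguistic,visual `embedding_system` objects with modality
#'   `"linguistic"` and `"visual"` respectively.
#' @return An object of class `bimodal_system`: list with elements
#'   `linguistic`, `visual`, `words`.
#' @export
pair_systems <- function(linguistic, visual) {
  stopifnot(inherits(linguistic, "embedding_system"),
            inherits(visual, "embedding_system"))
  if (linguistic$modality != "linguistic" || visual$modality != "visual") {
    stop("pair_systems() expects a linguistic and a visual system, got '",
         linguistic$modality, "' and '", visual$modality, "'")
  }
  only_l <- setdiff(linguistic$words, visual$words)
  only_v <- setdiff(visual$words, linguistic$words)
  if (length(only_l) || length(only_v)) {
    stop("word sets differ; only linguistic: {",
         paste(only_l, collapse = ", "), "}; only visual: {",
         paste(only_v, collapse = ", "), "}")
  }
  if (!identical(visual$words, linguistic$words)) {
    visual <- embedding_system(linguistic$words,
                               visual$exemplars[linguistic$words],
                               modality = "visual")
  }
  structure(
    list(linguistic = linguistic, visual = visual, words = linguistic$words),
    class = "bimodal_system"
  )
}

#' @export
print.bimodal_system <- function(x, ...) {
  cat("Bimodal system: ", length(x$words), " words; linguistic d = ",
      x$linguistic$d, ", visual d = ", x$visual$d, "\n", sep = "")
  invisible(x)
}

#' Pipeline configuration
#'
#' Bundles the Monte Carlo settings of the pipeline. The defaults are the
#' full-scale settings of the analyses this package implements: 1,000
#' permutations per relative-alignment evaluation, 1,000 simulations per level
#' of the one-dimensional aggregation curves, 500 simulations per cell of the
#' two-dimensional aggregation grid, and 20-exemplar prototypes for the fixed
#' modality. All counts can be reduced for exploratory runs.
#'
#' @param n_permutations Permutations drawn per relative-alignment evaluation.
#' @param n_simulations_1d Simulations per exemplar-count level of an
#'   aggregation curve.
#' @param n_simulations_2d Simulations per cell of an aggregation grid.
#' @param prototype_size Exemplars averaged into the fixed modality's
#'   prototype during one-dimensional aggregation.
#' @param seed Integer root seed. Each stochastic stage derives its own
#'   substream from it (see [derive_seed()]), so stages are reproducible in
#'   isolation.
#' @param ci_level Confidence level for bootstrap intervals, in (0, 1).
#' @param n_bootstrap Bootstrap resamples for confidence intervals.
#' @return An object of class `run_config`.
#' @export
run_config <- function(n_permutations = 1000L, n_simulations_1d = 1000L,
                       n_simulations_2d = 500L, prototype_size = 20L,
                       seed = 1L, ci_level = 0.95, n_bootstrap = 1000L) {
  counts <- c(n_permutations = n_permutations,
              n_simulations_1d = n_simulations_1d,
              n_simulations_2d = n_simulations_2d,
              prototype_size = prototype_size,
              n_bootstrap = n_bootstrap)
  if (any(counts < 1)) {
    stop("all counts must be >= 1; offending: ",
         paste(names(counts)[counts < 1], collapse = ", "))
  }
  if (!(ci_level > 0 && ci_level < 1)) stop("ci_level must be in (0, 1)")
  structure(
    list(n_permutations = as.integer(n_permutations),
         n_simulations_1d = as.integer(n_simulations_1d),
         n_simulations_2d = as.integer(n_simulations_2d),
         prototype_size = as.integer(prototype_size),
         seed = as.integer(seed),
         ci_level = ci_level,
         n_bootstrap = as.integer(n_bootstrap)),
    class = "run_config"
  )
}

#' Read a pipeline configuration from JSON or YAML
#'
#' The file holds any subset of [run_config()]'s fields; missing fields keep
#' their defaults.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  fields <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    stop("unrecognized config extension '", ext, "' (expected json/yaml)")
  }
  known <- names(formals(run_config))
  unknown <- setdiff(names(fields), known)
  if (length(unknown)) stop("unknown config fields: ", paste(unknown, collapse = ", "))
  do.call(run_config, fields)
}

#' Derive a stage-specific seed from a root seed
#'
#' Stochastic stages each draw from an independent, reproducible substream:
#' the root seed is hashed together with a stage label so that re-running one
#' stage in isolation reproduces its stream regardless of what ran before.
#' The result always fits in a 32-bit integer.
#'
#' @param seed Integer root seed.
#' @param label Character stage label, e.g. `"alignment"`.
#' @return A positive integer seed.
#' @export
derive_seed <- function(seed, label) {
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 131 + ch) %% 2147483647
  as.integer((abs(as.numeric(seed)) * 2654435761 + h) %% 2147483629 + 1)
}
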