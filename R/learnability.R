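#' Estimate age of acquisition from a proportion-knowing curve
#'
#' Age of acquisition (AoA) is the age, in months, at which half the children
#' in a corpus demonstrate understanding of a word. The curve of proportion
#' knowing against age is fit with a two-parameter logistic
#' `p(age) = 1 / (1 + exp(-(age - midpoint) / scale))`
#' by least squares (Levenberg-Marquardt) and the fitted midpoint is the AoA.
#' If the observed proportions never bracket 0.5 the estimate would be an
#' extrapolation; the result is then flagged out-of-range and `aoa_months` is
#' `NA` (the raw fitted midpoint remains available in `midpoint`).
#'
#' @param curve Data frame with columns `age_months` and
#'   `proportion_knowing` (>= 3 distinct ages, proportions in [0, 1]).
#' @return Object of class `aoa_estimate`: list with `aoa_months`,
#'   `midpoint`, `scale`, `out_of_range`.
#' @export
estimate_aoa <- function(curve) {
  if (!all(c("age_months", "proportion_knowing") %in% names(curve))) {
    stop("curve needs columns age_months and proportion_knowing")
  }
  age <- as.numeric(curve$age_months)
  p <- as.numeric(curve$proportion_knowing)
  if (length(age) < 3L || length(unique(age)) < 3L) {
    stop("need at least 3 distinct age points")
  }
  if (anyNA(age) || anyNA(p) || any(p < 0 | p > 1)) {
    stop("proportions must be in [0, 1] with no missing values")
  }
  # starting values from a linear fit on the logit scale
  p_clip <- pmin(pmax(p, 0.01), 0.99)
  lf <- stats::lm(stats::qlogis(p_clip) ~ age)
  slope <- unname(stats::coef(lf)[2])
  start <- list(
    midpoint = if (abs(slope) > 1e-8) -unname(stats::coef(lf)[1]) / slope
               else mean(age),
    scale = if (abs(slope) > 1e-8) 1 / slope else diff(range(age)) / 4
  )
  fit <- minpack.lm::nlsLM(
    p ~ 1 / (1 + exp(-(age - midpoint) / scale)),
    start = start,
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  est <- stats::coef(fit)
  out_of_range <- !(min(p) <= 0.5 && max(p) >= 0.5)
  structure(
    list(aoa_months = if (out_of_range) NA_real_ else unname(est["midpoint"]),
         midpoint = unname(est["midpoint"]),
         scale = unname(est["scale"]),
         out_of_range = out_of_range),
    class = "aoa_estimate"
  )
}

#' @export
print.aoa_estimate <- function(x, ...) {
  if (x$out_of_range) {
    cat(sprintf("AoA out of observed range (fitted midpoint %.1f months)\n",
                x$midpoint))
  } else {
    cat(sprintf("AoA = %.1f months (logistic midpoint)\n", x$aoa_months))
  }
  invisible(x)
}

aoa_feature_names <- function(table) {
  drop_cols <- c("word", "frequency", "aoa_months")
  feats <- setdiff(names(table), drop_cols)
  keep <- vapply(table[feats], is.numeric, logical(1))
  feats[keep]
}

#' Fit a gradient-boosted regression of age of acquisition on word features
#'
#' Trains an XGBoost regression-tree ensemble (squared-error objective) of
#' `aoa_months` on every numeric feature column of the table. The default
#' hyperparameters — 10,000 boosting rounds, maximum depth 10, learning rate
#' 0.02 — fit the table in-sample with no held-out split: the model is used
#' for explanation (feature attribution), not prediction on new words.
#' Tree models accommodate nonlinear feature effects and are insensitive to
#' the collinearity among the category-structure features. A single thread
#' and fixed seed make refits bit-identical.
#'
#' @param table Data frame with an `aoa_months` column and numeric feature
#'   columns (>= 20 rows). Columns `word` and raw `frequency` are ignored
#'   (use `log_frequency`).
#' @param nrounds,max_depth,learning_rate Boosting hyperparameters.
#' @param nthread Threads used by xgboost; 1 guarantees determinism.
#' @param seed Integer seed for xgboost's internal sampling.
#' @return Object of class `aoa_model`: list with `booster`, `features`,
#'   `table`.
#' @export
fit_aoa_model <- function(table, nrounds = 10000L, max_depth = 10L,
                          learning_rate = 0.02, nthread = 1L, seed = 1L) {
  if (!"aoa_months" %in% names(table)) stop("table needs an aoa_months column")
  if (nrow(table) < 20L) {
    stop("need at least 20 rows to fit the boosted model, got ", nrow(table))
  }
  features <- aoa_feature_names(table)
  if (length(features) == 0L) stop("no numeric feature columns found")
  x <- as.matrix(table[features])
  if (anyNA(x) || anyNA(table$aoa_months)) {
    stop("missing values in modeled rows are not allowed")
  }
  set.seed(seed)
  dtrain <- xgboost::xgb.DMatrix(x, label = table$aoa_months)
  booster <- xgboost::xgb.train(
    params = list(max_depth = max_depth, eta = learning_rate,
                  objective = "reg:squarederror", nthread = nthread,
                  seed = seed),
    data = dtrain, nrounds = nrounds, verbose = 0
  )
  structure(list(booster = booster, features = features, table = table),
            class = "aoa_model")
}

#' @export
predict.aoa_model <- function(object, newdata = NULL, ...) {
  tab <- if (is.null(newdata)) object$table else newdata
  missing <- setdiff(object$features, names(tab))
  if (length(missing)) stop("newdata lacks features: ",
                            paste(missing, collapse = ", "))
  x <- as.matrix(tab[object$features])
  stats::predict(object$booster, xgboost::xgb.DMatrix(x))
}

#' Shapley attributions of the fitted age-of-acquisition model
#'
#' Exact tree-path Shapley values (TreeSHAP) for every word and feature, in
#' months: a signed, additive decomposition of each prediction around the
#' model's base value, so for every word
#' `base_value + sum(attributions) = prediction` to numerical tolerance.
#'
#' @param model An `aoa_model`.
#' @param newdata Optional data frame with the model's feature columns;
#'   defaults to the training table.
#' @return Object of class `attribution_report`: list with `attributions`
#'   (word x feature matrix, months), `base_value`, `predictions`,
#'   `feature_values` (matrix of the attributed feature values).
#' @export
shap_attributions <- function(model, newdata = NULL) {
  stopifnot(inherits(model, "aoa_model"))
  tab <- if (is.null(newdata)) model$table else newdata
  missing <- setdiff(model$features, names(tab))
  if (length(missing)) stop("data lacks features: ",
                            paste(missing, collapse = ", "))
  x <- as.matrix(tab[model$features])
  dm <- xgboost::xgb.DMatrix(x)
  contrib <- stats::predict(model$booster, dm, predcontrib = TRUE)
  base_col <- ncol(contrib)  # bias column is last
  attributions <- contrib[, -base_col, drop = FALSE]
  rownames(attributions) <- if ("word" %in% names(tab)) tab$word else NULL
  structure(
    list(attributions = attributions,
         base_value = contrib[1, base_col],
         predictions = stats::predict(model$booster, dm),
         feature_values = x),
    class = "attribution_report"
  )
}

#' Global feature importance from Shapley attributions
#'
#' The global importance of a feature is the mean absolute attribution across
#' words, in months. Each feature's direction — whether high feature values
#' push the predicted age of acquisition up or down — is reported as the sign
#' of the Spearman correlation between feature value and attribution.
#'
#' @param report An `attribution_report`.
#' @return Data frame with columns `feature`, `importance`, `direction`,
#'   sorted by decreasing importance.
#' @export
global_importance <- function(report) {
  stopifnot(inherits(report, "attribution_report"))
  imp <- colMeans(abs(report$attributions))
  direction <- vapply(seq_along(imp), function(j) {
    a <- report$attributions[, j]
    v <- report$feature_values[, j]
    if (stats::sd(a) == 0 || stats::sd(v) == 0) return(0)
    sign(stats::cor(v, a, method = "spearman"))
  }, numeric(1))
  out <- data.frame(feature = names(imp), importance = unname(imp),
                    direction = direction, stringsAsFactors = FALSE)
  out[order(-out$importance), , drop = FALSE]
}

#' Assemble a learnability table from pipeline outputs
#'
#' Joins per-word category-structure metrics, the per-word alignment profile,
#' and a word-level table of type, frequency and age of acquisition into the
#' feature table consumed by [fit_aoa_model()].
#'
#' @param words_table Data frame with columns `word`, `word_type` (0 = noun,
#'   1 = verb), `frequency`, `aoa_months`.
#' @param structure_table The `table` element of [category_structure()].
#' @param alignment_profile Named numeric vector from
#'   [word_alignment_profile()].
#' @return Data frame with one modeled row per word, adding `log_frequency`
#'   (log10 of frequency) and `alignment`.
#' @export
build_learnability_table <- function(words_table, structure_table,
                                     alignment_profile) {
  need <- c("word", "word_type", "frequency", "aoa_months")
  missing <- setdiff(need, names(words_table))
  if (length(missing)) stop("words_table lacks columns: ",
                            paste(missing, collapse = ", "))
  if (any(words_table$frequency <= 0)) stop("frequencies must be positive")
  tab <- merge(words_table, structure_table, by = "word", sort = FALSE)
  tab$alignment <- alignment_profile[tab$word]
  tab$log_frequency <- log10(tab$frequency)
  if (anyNA(tab)) stop("missing values after joining learnability inputs")
  tab
}
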