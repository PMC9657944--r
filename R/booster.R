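#' Configuration for the gradient-boosted classification stage
#'
#' The boosting stage minimizes logistic loss plus a per-tree regularization
#' penalty (L2 weight `reg_lambda`, L1 weight `reg_alpha`) over an ensemble of
#' depth-limited trees — the standard regularized gradient-boosting objective.
#'
#' @param n_trees Number of boosting rounds.
#' @param max_depth Maximum tree depth.
#' @param learning_rate Shrinkage per round.
#' @param reg_lambda L2 penalty on leaf weights.
#' @param reg_alpha L1 penalty on leaf weights.
#' @param seed Integer seed; training is deterministic (single thread).
#' @return An `epi_booster_config`.
#' @export
booster_config <- function(n_trees = 200, max_depth = 6, learning_rate = 0.1,
                           reg_lambda = 1, reg_alpha = 0, seed = 1) {
  stopifnot(n_trees >= 1, max_depth >= 1, learning_rate > 0,
            reg_lambda >= 0, reg_alpha >= 0)
  structure(list(n_trees = as.integer(n_trees), max_depth = as.integer(max_depth),
                 learning_rate = learning_rate, reg_lambda = reg_lambda,
                 reg_alpha = reg_alpha, seed = as.integer(seed)),
            class = "epi_booster_config")
}

#' Train a per-target boosted classifier on molecular features
#'
#' @param features Numeric feature matrix (molecule embeddings or fingerprint
#'   bits), one row per molecule.
#' @param labels Binary labels: `active`/`inactive` character, or 0/1.
#' @param config An [booster_config()].
#' @param decision_threshold Probability cutoff for calling a molecule active.
#' @param target_id Optional label carried into reports.
#' @return An `epi_classifier` holding the fitted booster, the threshold, and
#'   a training report (class counts, training accuracy).
#' @export
train_booster <- function(features, labels, config = booster_config(),
                          decision_threshold = 0.5, target_id = NA_character_) {
  stopifnot(is.matrix(features))
  y <- as_binary_labels(labels)
  if (nrow(features) != length(y)) abort("feature/label length mismatch")
  if (anyNA(features)) abort("NaN/NA in feature matrix")
  if (length(unique(y)) < 2) abort("booster training needs both classes present")
  stopifnot(decision_threshold > 0, decision_threshold < 1)

  dtrain <- xgboost::xgb.DMatrix(features, label = y, nthread = 1)
  booster <- xgboost::xgb.train(
    params = list(objective = "binary:logistic",
                  max_depth = config$max_depth,
                  eta = config$learning_rate,
                  lambda = config$reg_lambda,
                  alpha = config$reg_alpha,
                  nthread = 1,
                  seed = config$seed),
    data = dtrain, nrounds = config$n_trees, verbose = 0
  )
  p <- predict(booster, dtrain)
  structure(list(
    target_id = target_id,
    booster_raw = xgboost::xgb.save.raw(booster),
    config = config,
    decision_threshold = decision_threshold,
    feature_dim = ncol(features),
    training_report = list(n = length(y), n_active = sum(y == 1),
                           n_inactive = sum(y == 0),
                           train_accuracy = mean((p >= decision_threshold) == y),
                           train_logloss = -mean(y * log(pmax(p, 1e-12)) +
                                                 (1 - y) * log(pmax(1 - p, 1e-12))))
  ), class = "epi_classifier")
}

as_binary_labels <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels)
    bad <- !labels %in% c("active", "inactive")
    if (any(bad)) abort(paste0("non-binary labels: ",
                               paste(unique(labels[bad]), collapse = ", ")))
    as.integer(labels == "active")
  } else {
    stopifnot(all(labels %in% c(0, 1)))
    as.integer(labels)
  }
}

#' @method print epi_classifier
#' @export
print.epi_classifier <- function(x, ...) {
  r <- x$training_report
  cat("<epi_classifier>", if (!is.na(x$target_id)) x$target_id else "",
      "|", r$n_active, "active /", r$n_inactive, "inactive |",
      x$config$n_trees, "trees | train acc",
      sprintf("%.3f", r$train_accuracy), "\n")
  invisible(x)
}

#' Predict activity probabilities and calls for a trained classifier
#'
#' @param object An `epi_classifier`.
#' @param features Feature matrix with the training feature dimension.
#' @param ... Unused.
#' @return A tibble with columns `probability` and `call`
#'   (`active`/`inactive`); `call` is active iff
#'   `probability >= decision_threshold`.
#' @export
predict.epi_classifier <- function(object, features, ...) {
  stopifnot(is.matrix(features))
  if (ncol(features) != object$feature_dim) {
    abort(paste0("feature dimension ", ncol(features),
                 " does not match training dimension ", object$feature_dim))
  }
  booster <- xgboost::xgb.load.raw(object$booster_raw)
  p <- predict(booster, xgboost::xgb.DMatrix(features, nthread = 1))
  tibble(probability = p,
         call = ifelse(p >= object$decision_threshold, "active", "inactive"))
}
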