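#' Confusion counts from binary truth and calls
#'
#' @param truth Character (`active`/`inactive`) or 0/1 vector of true labels.
#' @param call Predicted labels, same encoding.
#' @return An `epi_confusion`: named list with `tp`, `tn`, `fp`, `fn`.
#'   `active` is the positive class.
#' @export
confusion_counts <- function(truth, call) {
  yt <- as_binary_labels(truth)
  yp <- as_binary_labels(call)
  stopifnot(length(yt) == length(yp))
  structure(list(tp = sum(yt == 1 & yp == 1), tn = sum(yt == 0 & yp == 0),
                 fp = sum(yt == 0 & yp == 1), fn = sum(yt == 1 & yp == 0)),
            class = "epi_confusion")
}

as_confusion <- function(c) {
  if (inherits(c, "epi_confusion")) return(c)
  stopifnot(is.list(c) || is.numeric(c))
  c <- as.list(c)
  stopifnot(all(c("tp", "tn", "fp", "fn") %in% names(c)))
  structure(c[c("tp", "tn", "fp", "fn")], class = "epi_confusion")
}

#' Imbalance-aware binary classification metrics
#'
#' The Matthews correlation coefficient
#' \deqn{MCC = \frac{TP \cdot TN - FP \cdot FN}
#'   {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}}
#' the F1 score \eqn{F1 = 2TP / (2TP + FP + FN)}, and balanced accuracy
#' \eqn{BA = \frac{1}{2}\frac{TP}{TP+FN} + \frac{1}{2}\frac{TN}{TN+FP}}.
#' Metrics whose denominator is zero (a class or a call entirely absent) are
#' reported as `NA` ("undefined"), never silently coerced to 0.
#'
#' @param c An `epi_confusion` (or named list with tp/tn/fp/fn).
#' @return A single numeric value, or `NA` if undefined.
#' @export
mcc <- function(c) {
  c <- as_confusion(c)
  den <- (c$tp + c$fp) * (c$tp + c$fn) * (c$tn + c$fp) * (c$tn + c$fn)
  if (den == 0) return(NA_real_)
  (c$tp * c$tn - c$fp * c$fn) / sqrt(den)
}

#' @rdname mcc
#' @export
f1 <- function(c) {
  c <- as_confusion(c)
  den <- 2 * c$tp + c$fp + c$fn
  if (den == 0) return(NA_real_)
  2 * c$tp / den
}

#' @rdname mcc
#' @export
balanced_accuracy <- function(c) {
  c <- as_confusion(c)
  if (c$tp + c$fn == 0 || c$tn + c$fp == 0) return(NA_real_)
  0.5 * c$tp / (c$tp + c$fn) + 0.5 * c$tn / (c$tn + c$fp)
}

#' @rdname mcc
#' @export
precision_recall <- function(c) {
  c <- as_confusion(c)
  precision <- if (c$tp + c$fp == 0) NA_real_ else c$tp / (c$tp + c$fp)
  recall <- if (c$tp + c$fn == 0) NA_real_ else c$tp / (c$tp + c$fn)
  c(precision = precision, recall = recall)
}

#' Area under the ROC curve
#'
#' Computed with the midrank (Mann-Whitney) formula: the probability that a
#' random active scores above a random inactive, counting ties as one half.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (`active`/`inactive` or 0/1).
#' @return AUC in `[0, 1]`, or `NA` if only one class is present.
#' @export
roc_auc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  stopifnot(length(scores) == length(y))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

all_metrics <- function(truth, call, scores = NULL) {
  cc <- confusion_counts(truth, call)
  pr <- precision_recall(cc)
  tibble(tp = cc$tp, tn = cc$tn, fp = cc$fp, fn = cc$fn,
         mcc = mcc(cc), f1 = f1(cc), ba = balanced_accuracy(cc),
         precision = pr[["precision"]], recall = pr[["recall"]],
         auc = if (is.null(scores)) NA_real_ else roc_auc(scores, truth))
}

#' Stratified fold assignment
#'
#' Partitions records into `n_folds` folds, stratified by label so each fold
#' keeps approximately the global active fraction; reproducible from `seed`.
#'
#' @param labels Binary label vector.
#' @param n_folds Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold indices in `1..n_folds`.
#' @export
fold_plan <- function(labels, n_folds = 5, seed = 1) {
  y <- as_binary_labels(labels)
  stopifnot(n_folds >= 2)
  if (min(sum(y == 1), sum(y == 0)) < n_folds) {
    abort(paste0("need at least n_folds = ", n_folds,
                 " records of each class for stratified folds"))
  }
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in c(0, 1)) {
    ix <- sample(which(y == cls))
    fold[ix] <- rep_len(seq_len(n_folds), length(ix))
  }
  fold
}

#' Stratified train/test split
#'
#' @param data Data frame with a `label` column.
#' @param test_fraction Fraction held out.
#' @param seed Integer seed.
#' @return List with `train` and `test` tibbles.
#' @export
train_test_split <- function(data, test_fraction = 0.2, seed = 1) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  y <- as_binary_labels(data$label)
  set.seed(seed)
  test_ix <- integer(0)
  for (cls in c(0, 1)) {
    ix <- sample(which(y == cls))
    test_ix <- c(test_ix, ix[seq_len(max(1, round(length(ix) * test_fraction)))])
  }
  list(train = as_tibble(data[-test_ix, , drop = FALSE]),
       test = as_tibble(data[sort(test_ix), , drop = FALSE]))
}

#' Cross-validated evaluation of a featurizer + boosted classifier
#'
#' For each fold, the full pipeline is re-fit on the training split only: the
#' encoder never sees held-out molecules (no leakage), its embeddings feed a
#' fresh boosted classifier, and all metrics are computed on the held-out
#' fold. With `featurizer = "morgan"` the encoder stage is replaced by Morgan
#' fingerprint bits, giving the classical baseline under the identical
#' protocol.
#'
#' @param data Tibble with `smiles` and binary `label` for one target.
#' @param encoder An [encoder_config()] (ignored for the Morgan featurizer).
#' @param booster An [booster_config()].
#' @param n_folds Number of stratified folds.
#' @param seed Seed for the fold plan (the encoder/booster seeds come from
#'   their configs, offset per fold).
#' @param featurizer `"encoder"` or `"morgan"`.
#' @param scheme Feature scheme for graph building.
#' @param graphs Optional pre-built graphs aligned with `data`.
#' @param morgan_radius,morgan_bits Morgan baseline settings.
#' @return An `epi_cv` object: `folds` (per-fold metric tibble, including a
#'   hash of each fold's training compounds), `summary` (mean and sd per
#'   metric), and the configuration used. `tidy()` and `glance()` methods
#'   give the per-fold and aggregate views.
#' @export
crossvalidate <- function(data, encoder = encoder_config(),
                          booster = booster_config(), n_folds = 5, seed = 1,
                          featurizer = c("encoder", "morgan"),
                          scheme = feature_scheme(), graphs = NULL,
                          morgan_radius = 2, morgan_bits = 2048) {
  featurizer <- match.arg(featurizer)
  data <- as_tibble(data)
  stopifnot(all(c("smiles", "label") %in% names(data)))
  fold <- fold_plan(data$label, n_folds, seed)

  if (featurizer == "encoder" && is.null(graphs)) {
    graphs <- smiles_to_graphs(data$smiles, scheme,
                               ids = paste0("r", seq_len(nrow(data))))
    fails <- attr(graphs, "failures")
    if (nrow(fails) > 0) {
      abort(paste0("unparseable SMILES: ",
                   paste(utils::head(fails$smiles, 5), collapse = ", ")))
    }
  }
  fp_all <- if (featurizer == "morgan") {
    morgan_fingerprint(data$smiles, radius = morgan_radius, n_bits = morgan_bits)
  } else NULL

  rows <- vector("list", n_folds)
  for (k in seq_len(n_folds)) {
    tr <- which(fold != k); te <- which(fold == k)
    if (length(unique(data$label[tr])) < 2 || length(unique(data$label[te])) < 2) {
      abort("a fold lost a class; use stratified folds with more records")
    }
    if (featurizer == "encoder") {
      cfg <- encoder
      cfg$seed <- encoder$seed + k - 1L
      enc <- train_encoder(data[tr, ], cfg, scheme, graphs = graphs[tr])
      ftr <- embed(enc, graphs[tr])
      fte <- embed(enc, graphs[te])
    } else {
      ftr <- fp_all[tr, , drop = FALSE]
      fte <- fp_all[te, , drop = FALSE]
    }
    bcfg <- booster
    bcfg$seed <- booster$seed + k - 1L
    clf <- train_booster(ftr, data$label[tr], bcfg)
    pred <- predict(clf, fte)
    m <- all_metrics(data$label[te], pred$call, pred$probability)
    m$fold <- k
    m$n_train <- length(tr)
    m$n_test <- length(te)
    m$train_hash <- rlang::hash(sort(data$smiles[tr]))
    rows[[k]] <- m
  }
  folds <- bind_rows(rows) %>% select(all_of(c("fold", "n_train", "n_test")),
                                      dplyr::everything())
  metric_cols <- c("mcc", "f1", "ba", "precision", "recall", "auc")
  summary <- tidyr::pivot_longer(folds[, metric_cols], dplyr::everything(),
                                 names_to = "metric", values_to = "value") %>%
    group_by(.data$metric) %>%
    summarise(mean = mean(.data$value, na.rm = TRUE),
              sd = sd(.data$value, na.rm = TRUE), .groups = "drop") %>%
    mutate(metric = factor(.data$metric, levels = metric_cols)) %>%
    arrange(.data$metric) %>%
    mutate(metric = as.character(.data$metric))
  structure(list(folds = folds, summary = summary, featurizer = featurizer,
                 n_folds = n_folds, seed = seed,
                 encoder = if (featurizer == "encoder") encoder else NULL,
                 booster = booster),
            class = "epi_cv")
}

#' @method print epi_cv
#' @export
print.epi_cv <- function(x, ...) {
  cat("<epi_cv>", x$n_folds, "folds | featurizer:",
      if (x$featurizer == "encoder") toupper(x$encoder$kind) else "Morgan", "\n")
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-9s %.3f +/- %.3f\n", s$metric[i], s$mean[i], s$sd[i]))
  }
  invisible(x)
}

#' Pooled multi-target validation (TPR, NPV, FDR)
#'
#' Evaluates a multi-target model on compounds with at least two known active
#' targets, pooling (compound, target) pairs whose true label is known;
#' pairs with unknown labels are excluded from all counts. Reports the true
#' positive rate `TP/(TP+FN)`, negative predictive value `TN/(TN+FN)`, and
#' false discovery rate `FP/(FP+TP)`.
#'
#' @param model An `epi_multitarget` model.
#' @param records Long activity tibble (`compound_id`, `smiles`, `target_id`,
#'   `label`, where `label` may be `unknown`).
#' @param min_active_targets Eligibility threshold on known active targets
#'   per compound (default 2).
#' @param calls Optional precomputed prediction tibble
#'   ([predict_multitarget()] output); when supplied, `model` may be `NULL`
#'   and no prediction is run.
#' @return A one-row tibble: `tpr`, `npv`, `fdr`, plus pooled counts and the
#'   number of eligible compounds.
#' @export
multitarget_validation <- function(model, records, min_active_targets = 2,
                                   calls = NULL) {
  if (is.null(calls)) stopifnot(inherits(model, "epi_multitarget"))
  records <- as_tibble(records)
  eligible <- records %>%
    filter(.data$label == "active") %>%
    count(.data$compound_id) %>%
    filter(.data$n >= min_active_targets) %>%
    pull(.data$compound_id)
  if (length(eligible) == 0) {
    abort(paste0("no compound has at least ", min_active_targets,
                 " known active targets; multi-target validation set is empty"))
  }
  sub <- records %>% filter(.data$compound_id %in% eligible)
  preds <- if (is.null(calls)) {
    predict_multitarget(model, distinct(sub, .data$compound_id, .data$smiles))
  } else {
    as_tibble(calls)
  }
  joined <- sub %>%
    filter(.data$label %in% c("active", "inactive")) %>%
    left_join(preds, by = c("compound_id", "target_id")) %>%
    filter(!is.na(.data$call))
  cc <- confusion_counts(joined$label, joined$call)
  tibble(
    tpr = if (cc$tp + cc$fn == 0) NA_real_ else cc$tp / (cc$tp + cc$fn),
    npv = if (cc$tn + cc$fn == 0) NA_real_ else cc$tn / (cc$tn + cc$fn),
    fdr = if (cc$fp + cc$tp == 0) NA_real_ else cc$fp / (cc$fp + cc$tp),
    tp = cc$tp, tn = cc$tn, fp = cc$fp, fn = cc$fn,
    n_pairs = nrow(joined), n_compounds = length(eligible)
  )
}
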