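# broom-style tidiers for the fitted objects and result types.

#' Tidy a cross-validation result
#'
#' @param x An `epi_cv` from [crossvalidate()].
#' @param ... Unused.
#' @return Per-fold metrics in long tidy form (`fold`, `metric`, `value`).
#' @export
tidy.epi_cv <- function(x, ...) {
  tidyr::pivot_longer(x$folds,
                      all_of(c("mcc", "f1", "ba", "precision", "recall", "auc")),
                      names_to = "metric", values_to = "value") %>%
    select(all_of(c("fold", "n_train", "n_test", "metric", "value")))
}

#' @rdname tidy.epi_cv
#' @return For `glance()`: one row per metric with `mean` and `sd` across
#'   folds, plus the featurizer used.
#' @export
glance.epi_cv <- function(x, ...) {
  x$summary %>%
    mutate(featurizer = if (x$featurizer == "encoder") x$encoder$kind else "morgan",
           n_folds = x$n_folds)
}

#' Tidy a trained encoder
#'
#' @param x An `epi_encoder`.
#' @param ... Unused.
#' @return The training loss trajectory (`epoch`, `loss`).
#' @export
tidy.epi_encoder <- function(x, ...) {
  tibble(epoch = seq_along(x$loss_history), loss = x$loss_history)
}

#' @rdname tidy.epi_encoder
#' @export
glance.epi_encoder <- function(x, ...) {
  tibble(kind = x$config$kind, hidden_dim = x$config$hidden_dim,
         depth = x$config$depth, epochs = x$config$epochs,
         n_train = x$n_train, active_fraction = x$class_balance,
         final_loss = x$loss_history[length(x$loss_history)])
}

#' Tidy a per-target boosted classifier
#'
#' @param x An `epi_classifier`.
#' @param ... Unused.
#' @return One-row tibble with the training report.
#' @export
glance.epi_classifier <- function(x, ...) {
  r <- x$training_report
  tibble(target_id = x$target_id, n = r$n, n_active = r$n_active,
         n_inactive = r$n_inactive, n_trees = x$config$n_trees,
         train_accuracy = r$train_accuracy, train_logloss = r$train_logloss,
         decision_threshold = x$decision_threshold)
}

#' Tidy a multi-target model
#'
#' @param x An `epi_multitarget`.
#' @param ... Unused.
#' @return One row per target: group, class counts, training accuracy.
#' @export
tidy.epi_multitarget <- function(x, ...) {
  purrr::map_dfr(x$registry$target_id, function(tid) {
    g <- glance(x$models[[tid]]$classifier)
    g$object_group <- x$registry$object_group[x$registry$target_id == tid]
    g
  }) %>% select(all_of(c("target_id", "object_group")), dplyr::everything())
}

#' @rdname tidy.epi_multitarget
#' @export
glance.epi_multitarget <- function(x, ...) {
  tibble(n_targets = nrow(x$registry),
         n_groups = length(unique(x$registry$object_group)),
         encoder_kind = x$models[[1]]$encoder$config$kind,
         version = x$version)
}
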