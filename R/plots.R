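# ggplot2 views of the result types.

#' Plot per-fold metric distributions of a cross-validation run
#'
#' @param object An `epi_cv`.
#' @param ... Unused.
#' @return A ggplot: one panel strip of per-fold metric values.
#' @export
autoplot.epi_cv <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.12, height = 0, size = 1.6, alpha = 0.7) +
    ggplot2::ylim(NA, 1) +
    ggplot2::labs(x = NULL, y = "held-out value",
                  title = paste0("Cross-validated performance (",
                                 if (object$featurizer == "encoder")
                                   toupper(object$encoder$kind) else "Morgan",
                                 " features)")) +
    ggplot2::theme_minimal()
}

#' Compare per-target AUC between featurizers
#'
#' Draws the featurizer-comparison view: one point per target per featurizer,
#' from a table with columns `target_id`, `featurizer`, `auc`.
#'
#' @param auc_table Tibble with `target_id`, `featurizer`, `auc`.
#' @return A ggplot.
#' @export
plot_auc_comparison <- function(auc_table) {
  stopifnot(all(c("target_id", "featurizer", "auc") %in% names(auc_table)))
  ggplot2::ggplot(auc_table,
                  ggplot2::aes(x = .data$target_id, y = .data$auc,
                               fill = .data$featurizer)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_cartesian(ylim = c(0.5, 1)) +
    ggplot2::labs(x = "target", y = "cross-validated AUC", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Heatmap of per-compound polypharmacology significance
#'
#' @param object An `epi_polypharm` from [polypharmacology_report()].
#' @param ... Unused.
#' @return A ggplot tile map: compounds x object groups, filled by -log10 p,
#'   significant cells outlined.
#' @export
autoplot.epi_polypharm <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$object_group, y = .data$compound_id,
                               fill = -log10(.data$p_value))) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::geom_point(data = object[object$significant, , drop = FALSE],
                        shape = 8, size = 2) +
    ggplot2::scale_fill_gradient(low = "grey95", high = "firebrick") +
    ggplot2::labs(x = "object group", y = NULL, fill = "-log10 p",
                  caption = "* group enrichment p < alpha") +
    ggplot2::theme_minimal()
}
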