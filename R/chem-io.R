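#' Binarize potency values at the 10 uM activity threshold
#'
#' Compounds with a potency (IC50/EC50/Ki/Kd) lower than or equal to 10 uM are
#' labelled active; values strictly above 10 uM are labelled inactive.
#'
#' @param value_um Numeric vector of potency values in micromolar.
#' @param threshold_um Activity cutoff, default 10 uM.
#' @param ids Optional record identifiers used in validation messages.
#' @return Character vector of `"active"` / `"inactive"`.
#' @examples
#' binarize_activity(c(10, 10.000001, 0.001))
#' @export
binarize_activity <- function(value_um, threshold_um = 10, ids = NULL) {
  bad <- !is.finite(value_um) | value_um <= 0
  if (any(bad)) {
    which_bad <- if (is.null(ids)) paste0("record ", which(bad)) else ids[bad]
    abort(paste0("activity values must be finite and positive (uM); offending: ",
                 paste(head(which_bad, 5), collapse = ", ")))
  }
  ifelse(value_um <= threshold_um, "active", "inactive")
}

#' Build a target registry
#'
#' A registry is an ordered table of protein targets with the epigenetic
#' object group (protein family) each belongs to.
#'
#' @param target_id Character vector of target identifiers.
#' @param object_group Character vector of family names (e.g. HDAC, HMT, HDM,
#'   HAT, DNMT), one per target.
#' @param groups The declared finite set of admissible group names.
#' @return A tibble of class `epi_registry` with columns `target_id`,
#'   `object_group`.
#' @export
target_registry <- function(target_id, object_group,
                            groups = c("HDAC", "HMT", "HDM", "HAT", "DNMT")) {
  stopifnot(length(target_id) == length(object_group))
  if (anyDuplicated(target_id)) abort("duplicate target_id in registry")
  unknown <- setdiff(unique(object_group), groups)
  if (length(unknown) > 0) {
    abort(paste0("object groups outside the declared set: ",
                 paste(unknown, collapse = ", ")))
  }
  out <- tibble(target_id = as.character(target_id),
                object_group = as.character(object_group))
  class(out) <- c("epi_registry", class(out))
  out
}

#' Read a long-format compound-activity table
#'
#' Expects a UTF-8 CSV with header and columns `compound_id`, `smiles`,
#' `target_id`, and at least one of `activity_um` (potency in uM) or `label`
#' (`active`/`inactive`/`unknown`). Missing labels are derived from
#' `activity_um` by the 10 uM rule; `unknown` labels are preserved, never
#' imputed. Rows duplicated with identical labels are deduplicated; duplicate
#' (compound, target) pairs with conflicting labels are an error.
#'
#' @param path CSV file (long format) or a directory of per-target CSVs named
#'   `<target_id>.csv` (each with `compound_id`, `smiles`, and `activity_um`
#'   and/or `label`).
#' @param format `"long_csv"` or `"per_target_csv"`.
#' @param threshold_um Binarization cutoff passed to [binarize_activity()].
#' @return A tibble of validated records (`compound_id`, `smiles`,
#'   `target_id`, `activity_um`, `label`) with a `report` attribute: per-target
#'   counts of parsed, active, inactive and unknown records.
#' @export
read_activity_data <- function(path, format = c("long_csv", "per_target_csv"),
                               threshold_um = 10) {
  format <- match.arg(format)
  if (format == "long_csv") {
    df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    files <- list.files(path, pattern = "\\.csv$", full.names = TRUE)
    if (length(files) == 0) abort(paste0("no per-target CSV files under ", path))
    df <- purrr::map_dfr(files, function(f) {
      d <- readr::read_csv(f, show_col_types = FALSE, progress = FALSE)
      d$target_id <- sub("\\.csv$", "", basename(f))
      d
    })
  }
  validate_activity_table(as_tibble(df), threshold_um)
}

validate_activity_table <- function(df, threshold_um = 10) {
  required <- c("compound_id", "smiles", "target_id")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("missing required columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (!("activity_um" %in% names(df)) && !("label" %in% names(df))) {
    abort("need at least one of columns 'activity_um' or 'label'")
  }
  if (!("activity_um" %in% names(df))) df$activity_um <- NA_real_
  if (!("label" %in% names(df))) df$label <- NA_character_
  df <- df %>%
    mutate(compound_id = as.character(.data$compound_id),
           smiles = as.character(.data$smiles),
           target_id = as.character(.data$target_id),
           activity_um = as.numeric(.data$activity_um),
           label = as.character(.data$label)) %>%
    select(all_of(c("compound_id", "smiles", "target_id", "activity_um", "label")))

  if (nrow(df) == 0) {
    warn("activity table is empty (header only)")
    attr(df, "report") <- tibble(target_id = character(), n = integer(),
                                 active = integer(), inactive = integer(),
                                 unknown = integer())
    return(df)
  }

  derive <- is.na(df$label) & !is.na(df$activity_um)
  if (any(derive)) {
    df$label[derive] <- binarize_activity(df$activity_um[derive], threshold_um,
                                          ids = df$compound_id[derive])
  }
  df$label[is.na(df$label)] <- "unknown"
  bad_label <- !df$label %in% c("active", "inactive", "unknown")
  if (any(bad_label)) {
    abort(paste0("invalid label values: ",
                 paste(unique(df$label[bad_label]), collapse = ", ")))
  }

  # a stated label must not contradict a stated activity value
  has_both <- !is.na(df$activity_um) & df$label != "unknown"
  if (any(has_both)) {
    implied <- binarize_activity(df$activity_um[has_both], threshold_um,
                                 ids = df$compound_id[has_both])
    clash <- implied != df$label[has_both]
    if (any(clash)) {
      abort(paste0("label contradicts the ", threshold_um, " uM rule for: ",
                   paste(head(unique(df$compound_id[has_both][clash]), 5),
                         collapse = ", ")))
    }
  }

  df <- distinct(df, .data$compound_id, .data$target_id, .data$label, .keep_all = TRUE)
  conflicts <- df %>%
    count(.data$compound_id, .data$target_id) %>%
    filter(.data$n > 1)
  if (nrow(conflicts) > 0) {
    abort(paste0("conflicting labels for (compound, target) pairs: ",
                 paste(head(paste0(conflicts$compound_id, "/", conflicts$target_id), 5),
                       collapse = ", ")))
  }
  # one SMILES per compound
  multi_smiles <- df %>% distinct(.data$compound_id, .data$smiles) %>%
    count(.data$compound_id) %>% filter(.data$n > 1)
  if (nrow(multi_smiles) > 0) {
    abort(paste0("compound ids with more than one SMILES: ",
                 paste(head(multi_smiles$compound_id, 5), collapse = ", ")))
  }

  report <- df %>%
    group_by(.data$target_id) %>%
    summarise(n = n(),
              active = sum(.data$label == "active"),
              inactive = sum(.data$label == "inactive"),
              unknown = sum(.data$label == "unknown"),
              .groups = "drop")
  attr(df, "report") <- report
  df
}

#' Write a compound-activity table back to CSV
#'
#' Inverse of [read_activity_data()] (long format): the written file reads
#' back to an identical record table.
#'
#' @param records Tibble as returned by [read_activity_data()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_activity_data <- function(records, path) {
  readr::write_csv(records, path, progress = FALSE)
  invisible(path)
}

#' Per-target active/inactive counts
#'
#' @param records Activity table (long tibble with `target_id`, `label`).
#' @return Tibble with columns `target_id`, `active`, `inactive`, `unknown`.
#' @export
target_class_counts <- function(records) {
  records %>%
    group_by(.data$target_id) %>%
    summarise(active = sum(.data$label == "active"),
              inactive = sum(.data$label == "inactive"),
              unknown = sum(.data$label == "unknown"),
              .groups = "drop")
}

#' Drop targets with too few compounds per class
#'
#' A target is retained only if it has at least `min_per_class` active and at
#' least `min_per_class` inactive compounds (the dataset-preparation rule that
#' makes a per-target binary task trainable). Dropped targets and their counts
#' are reported via the `dropped` attribute and a message.
#'
#' @param records Activity table with binarized labels.
#' @param registry An `epi_registry`.
#' @param min_per_class Minimum count per class, default 30.
#' @return The filtered registry (same class), with attribute `dropped`.
#' @export
filter_targets <- function(records, registry, min_per_class = 30) {
  if (nrow(records) == 0) abort("empty record list")
  counts <- target_class_counts(records)
  counts <- left_join(registry, counts, by = "target_id") %>%
    mutate(active = ifelse(is.na(.data$active), 0L, .data$active),
           inactive = ifelse(is.na(.data$inactive), 0L, .data$inactive))
  keep <- counts$active >= min_per_class & counts$inactive >= min_per_class
  dropped <- counts[!keep, c("target_id", "active", "inactive")]
  if (all(!keep)) {
    abort(paste0("no target survives the >=", min_per_class, "-per-class filter; counts: ",
                 paste(paste0(counts$target_id, " (", counts$active, "a/",
                              counts$inactive, "i)"), collapse = ", ")))
  }
  if (nrow(dropped) > 0) {
    inform(paste0("filter_targets: dropped ", nrow(dropped), " target(s): ",
                  paste(paste0(dropped$target_id, " (", dropped$active, "a/",
                               dropped$inactive, "i)"), collapse = ", ")))
  }
  out <- registry[keep[match(registry$target_id, counts$target_id)], ]
  attr(out, "dropped") <- dropped
  out
}
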