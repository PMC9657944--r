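#' Fit a multi-target activity predictor
#'
#' Trains one encoder + boosted classifier per registry target on that
#' target's labelled records (unknown labels are skipped) and assembles them
#' into a single multi-target model. Assembly introduces no coupling: the
#' multi-target prediction for (molecule, target) is exactly the output of
#' that target's single-target classifier.
#'
#' @param records Long activity tibble (`compound_id`, `smiles`, `target_id`,
#'   `label`).
#' @param registry An `epi_registry` of targets and object groups.
#' @param encoder An [encoder_config()]; each target gets its own encoder
#'   (seed offset by target index).
#' @param booster An [booster_config()].
#' @param scheme A [feature_scheme()].
#' @param graphs Optional named list of pre-built graphs keyed by
#'   `compound_id`.
#' @return An `epi_multitarget` with per-target `(encoder, classifier)` pairs
#'   in registry order.
#' @export
fit_multitarget <- function(records, registry, encoder = encoder_config(),
                            booster = booster_config(),
                            scheme = feature_scheme(), graphs = NULL) {
  records <- as_tibble(records)
  stopifnot(inherits(registry, "epi_registry"))
  extra <- setdiff(unique(records$target_id), registry$target_id)
  if (length(extra) > 0) {
    abort(paste0("records mention targets missing from the registry: ",
                 paste(extra, collapse = ", ")))
  }
  if (is.null(graphs)) {
    mols <- distinct(records, .data$compound_id, .data$smiles)
    graphs <- smiles_to_graphs(mols$smiles, scheme, ids = mols$compound_id)
    fails <- attr(graphs, "failures")
    if (nrow(fails) > 0) {
      abort(paste0("unparseable SMILES for compounds: ",
                   paste(utils::head(fails$id, 5), collapse = ", ")))
    }
  }
  models <- vector("list", nrow(registry))
  names(models) <- registry$target_id
  for (j in seq_len(nrow(registry))) {
    tid <- registry$target_id[j]
    sub <- records %>% filter(.data$target_id == tid,
                              .data$label %in% c("active", "inactive"))
    ecfg <- encoder; ecfg$seed <- encoder$seed + j - 1L
    bcfg <- booster; bcfg$seed <- booster$seed + j - 1L
    enc <- train_encoder(sub, ecfg, scheme, graphs = graphs[sub$compound_id])
    feats <- embed(enc, graphs[sub$compound_id])
    clf <- train_booster(feats, sub$label, bcfg, target_id = tid)
    models[[j]] <- list(encoder = enc, classifier = clf)
  }
  structure(list(registry = registry, models = models, scheme = scheme,
                 version = as.character(utils::packageVersion("epitarget"))),
            class = "epi_multitarget")
}

#' @method print epi_multitarget
#' @export
print.epi_multitarget <- function(x, ...) {
  cat("<epi_multitarget>", nrow(x$registry), "targets in",
      length(unique(x$registry$object_group)), "object groups |",
      toupper(x$models[[1]]$encoder$config$kind), "+ boosted trees\n")
  invisible(x)
}

#' Predict per-target activity for a set of molecules
#'
#' Runs every single-target classifier on each molecule. Unparseable SMILES
#' are reported per molecule; remaining rows are still computed.
#'
#' @param model An `epi_multitarget`.
#' @param data Tibble with `compound_id` and `smiles` (or a character vector
#'   of SMILES, in which case ids are generated).
#' @return A long tibble (`compound_id`, `target_id`, `probability`, `call`)
#'   with targets in registry order; carries a `failures` attribute listing
#'   molecules that could not be parsed.
#' @export
predict_multitarget <- function(model, data) {
  stopifnot(inherits(model, "epi_multitarget"))
  if (is.character(data)) {
    data <- tibble(compound_id = paste0("q", seq_along(data)), smiles = data)
  }
  data <- distinct(as_tibble(data), .data$compound_id, .data$smiles)
  graphs <- smiles_to_graphs(data$smiles, model$scheme, ids = data$compound_id)
  fails <- attr(graphs, "failures")
  okids <- data$compound_id[!vapply(graphs, is.null, logical(1))]
  graphs <- graphs[okids]
  if (length(okids) == 0) {
    out <- tibble(compound_id = character(), target_id = character(),
                  probability = numeric(), call = character())
    attr(out, "failures") <- fails
    return(out)
  }
  res <- purrr::map_dfr(model$registry$target_id, function(tid) {
    mt <- model$models[[tid]]
    feats <- embed(mt$encoder, graphs)
    pred <- predict(mt$classifier, feats)
    tibble(compound_id = okids, target_id = tid,
           probability = pred$probability, call = pred$call)
  })
  out <- res %>%
    mutate(target_id = factor(.data$target_id, levels = model$registry$target_id)) %>%
    arrange(match(.data$compound_id, okids), .data$target_id) %>%
    mutate(target_id = as.character(.data$target_id))
  attr(out, "failures") <- fails
  out
}

#' Upper-tail hypergeometric probability
#'
#' Exact probability of observing at least `k` successes when drawing `n`
#' items without replacement from a population of `N` containing `K`
#' successes:
#' \deqn{P(X \ge k) = \sum_{j=k}^{\min(n,K)} \frac{\binom{K}{j}\binom{N-K}{n-j}}{\binom{N}{n}}}
#'
#' @param N Population size (total registered targets).
#' @param K Successes in the population (targets in the object group).
#' @param n Draws (the compound's predicted-active targets).
#' @param k Observed successes (predicted-active within the group).
#' @return The exact tail probability in `(0, 1]`. Vectorized.
#' @examples
#' hypergeom_pvalue(24, 10, 5, 5)  # == choose(10,5)/choose(24,5)
#' @export
hypergeom_pvalue <- function(N, K, n, k) {
  v <- vctrs_recycle(N, K, n, k)
  N <- v[[1]]; K <- v[[2]]; n <- v[[3]]; k <- v[[4]]
  bad <- K > N | n > N | k > pmin(n, K) | k < 0 | N < 0 | K < 0 | n < 0 |
    k < pmax(0, n + K - N)
  if (any(bad)) {
    abort(paste0("inconsistent hypergeometric counts at position ",
                 paste(which(bad), collapse = ", "),
                 " (need 0 <= k <= min(n, K), K <= N, n <= N, k >= max(0, n+K-N))"))
  }
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

vctrs_recycle <- function(...) {
  xs <- list(...)
  len <- max(vapply(xs, length, integer(1)))
  lapply(xs, rep_len, len)
}

#' Per-compound polypharmacology report with hypergeometric enrichment
#'
#' For each compound, counts its predicted-active targets (`n`) and, within
#' each object group of size `K` (out of `N` registered targets), the
#' predicted-active targets in the group (`k`); the group is flagged
#' significant when the upper-tail hypergeometric probability of drawing at
#' least `k` group members in `n` draws falls below `alpha`. Compounds with
#' no predicted-active target report `p = 1` for every group. P-values are
#' reported raw (no correction across groups) by default, matching the
#' convention of flagging groups at p < 0.05; `correct = "bonferroni"`
#' multiplies by the number of groups.
#'
#' @param model An `epi_multitarget`.
#' @param data Molecules to profile (as in [predict_multitarget()]), or a
#'   precomputed prediction tibble from [predict_multitarget()] passed via
#'   `calls`.
#' @param alpha Significance level (default 0.05).
#' @param correct `"none"` (default) or `"bonferroni"`.
#' @param calls Optional precomputed long prediction tibble.
#' @return A tibble of class `epi_polypharm`: one row per compound x group
#'   with `k`, `K`, `n`, `N`, `p_value`, `significant`.
#' @export
polypharmacology_report <- function(model, data = NULL, alpha = 0.05,
                                    correct = c("none", "bonferroni"),
                                    calls = NULL) {
  correct <- match.arg(correct)
  stopifnot(alpha > 0, alpha < 1)
  registry <- model$registry
  if (length(unique(registry$object_group)) < 2) {
    abort("polypharmacology report needs a registry with at least 2 object groups")
  }
  if (is.null(calls)) {
    if (is.null(data)) abort("provide molecules (data) or precomputed calls")
    calls <- predict_multitarget(model, data)
  }
  out <- polypharm_from_calls(calls, registry, alpha, correct)
  class(out) <- c("epi_polypharm", class(out))
  out
}

# pure assembly of the group-level enrichment table from per-target calls
polypharm_from_calls <- function(calls, registry, alpha = 0.05,
                                 correct = "none") {
  N <- nrow(registry)
  group_sizes <- registry %>% count(.data$object_group, name = "K")
  per_compound <- calls %>%
    left_join(registry, by = "target_id") %>%
    group_by(.data$compound_id) %>%
    mutate(n_active_total = sum(.data$call == "active")) %>%
    group_by(.data$compound_id, .data$object_group, .data$n_active_total) %>%
    summarise(k = sum(.data$call == "active"), .groups = "drop") %>%
    left_join(group_sizes, by = "object_group") %>%
    rename(n = "n_active_total")
  n_groups <- nrow(group_sizes)
  out <- per_compound %>%
    mutate(N = N,
           p_value = hypergeom_pvalue(N, .data$K, .data$n, .data$k),
           p_value = if (correct == "bonferroni") {
             pmin(1, .data$p_value * n_groups)
           } else .data$p_value,
           significant = .data$p_value < alpha) %>%
    select(all_of(c("compound_id", "object_group", "k", "K", "n", "N",
                    "p_value", "significant")))
  out
}

#' Save / load a multi-target model archive
#'
#' The archive is a directory holding a JSON manifest (registry, feature
#' scheme fingerprint, package version) plus one serialized model pair per
#' target. Loading refuses archives whose manifest is missing or whose
#' feature-scheme fingerprint does not match the stored models.
#'
#' @param model An `epi_multitarget`.
#' @param path Archive directory (created if needed).
#' @return `save_multitarget()` returns `path` invisibly; `load_multitarget()`
#'   returns the restored `epi_multitarget`.
#' @export
save_multitarget <- function(model, path) {
  stopifnot(inherits(model, "epi_multitarget"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(
    package = "epitarget",
    version = model$version,
    scheme_fingerprint = model$scheme$fingerprint,
    encoder_kind = model$models[[1]]$encoder$config$kind,
    targets = model$registry$target_id,
    object_groups = model$registry$object_group
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  saveRDS(model$scheme, file.path(path, "scheme.rds"))
  for (tid in model$registry$target_id) {
    saveRDS(model$models[[tid]], file.path(path, paste0("target_", tid, ".rds")))
  }
  invisible(path)
}

#' @rdname save_multitarget
#' @export
load_multitarget <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) abort(paste0("not a model archive (missing manifest.json): ", path))
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  scheme <- readRDS(file.path(path, "scheme.rds"))
  if (!identical(manifest$scheme_fingerprint, scheme$fingerprint)) {
    abort("archive manifest does not match stored feature scheme")
  }
  models <- list()
  for (tid in manifest$targets) {
    f <- file.path(path, paste0("target_", tid, ".rds"))
    if (!file.exists(f)) abort(paste0("archive is missing model file for target ", tid))
    models[[tid]] <- readRDS(f)
    if (!identical(models[[tid]]$encoder$scheme$fingerprint,
                   manifest$scheme_fingerprint)) {
      abort(paste0("feature-scheme mismatch for target ", tid))
    }
  }
  registry <- target_registry(manifest$targets, manifest$object_groups,
                              groups = unique(manifest$object_groups))
  structure(list(registry = registry, models = models, scheme = scheme,
                 version = manifest$version),
            class = "epi_multitarget")
}
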