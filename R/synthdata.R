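# Synthetic compound-activity datasets with planted structure-activity rules.
# Molecules are assembled valence-safely from drug-like fragments; a target's
# activity label is determined by the presence of that target's substructure
# motif (then optionally flipped by label noise), so every pipeline stage can
# be exercised without any external database.

# Divalent chain fragments, deliberately free of N/O heteroatoms so that no
# planted motif can arise by accidental fragment adjacency.
SYNTH_INNER <- c("C", "CC", "CCC", "C(C)C", "c1ccc(cc1)")
SYNTH_START <- c("C", "CC", "CCC", "c1ccccc1", "C(C)(C)C")
SYNTH_END <- c("C", "CC", "c1ccccc1", "C(C)C")

# Planted motifs: a divalent SMILES chunk and the SMARTS pattern that detects
# it. Each motif is detectable within 3 bond hops.
SYNTH_MOTIFS <- list(
  amide = list(chunk = "C(=O)N", smarts = "[CX3](=O)[NX3]"),
  ester = list(chunk = "C(=O)O", smarts = "[CX3](=O)[OX2][#6]"),
  sulfonamide = list(chunk = "S(=O)(=O)N", smarts = "[SX4](=O)(=O)[NX3]"),
  nitrile = list(chunk = "C(C#N)", smarts = "[CX2]#[NX1]"),
  pyridine = list(chunk = "c1ncc(cc1)", smarts = "[n]")
)

#' Specification for a synthetic multi-target activity dataset
#'
#' @param n_molecules Number of compounds to generate.
#' @param targets Named list mapping `target_id` to a motif name from
#'   `names(epitarget:::SYNTH_MOTIFS)` (amide, ester, sulfonamide, nitrile,
#'   pyridine), or `NULL` for the default five-target panel.
#' @param object_groups Optional named character vector `target_id -> group`;
#'   defaults to cycling through HDAC, HMT, HDM, HAT, DNMT.
#' @param label_noise Probability that a motif-derived label is flipped
#'   (`0 <= noise < 0.5`).
#' @param active_fraction Target prevalence of actives per target
#'   (probability that a target's motif is planted in a molecule).
#' @param seed Integer seed; generation is fully reproducible.
#' @return An object of class `epi_synth_spec`.
#' @export
synth_spec <- function(n_molecules = 1000, targets = NULL, object_groups = NULL,
                       label_noise = 0.1, active_fraction = 0.5, seed = 1) {
  if (is.null(targets)) {
    targets <- as.list(setNames(names(SYNTH_MOTIFS),
                                paste0("T", seq_along(SYNTH_MOTIFS))))
  }
  stopifnot(label_noise >= 0, label_noise < 0.5,
            active_fraction > 0, active_fraction < 1,
            n_molecules >= 1)
  bad <- setdiff(unlist(targets), names(SYNTH_MOTIFS))
  if (length(bad) > 0) abort(paste0("unknown motif name(s): ", paste(bad, collapse = ", ")))
  if (is.null(object_groups)) {
    grp <- c("HDAC", "HMT", "HDM", "HAT", "DNMT")
    object_groups <- setNames(rep_len(grp, length(targets)), names(targets))
  }
  structure(list(
    n_molecules = as.integer(n_molecules),
    targets = targets,
    object_groups = object_groups,
    label_noise = label_noise,
    active_fraction = active_fraction,
    seed = as.integer(seed)
  ), class = "epi_synth_spec")
}

# assemble one molecule: start + shuffled (inner chunks + motif chunks) + end,
# with motifs never in terminal position
assemble_smiles <- function(motif_chunks, rng_n_inner) {
  n_inner <- rng_n_inner
  inner <- sample(SYNTH_INNER, n_inner, replace = TRUE)
  mid <- c(inner, motif_chunks)
  mid <- sample(mid, length(mid))
  paste0(sample(SYNTH_START, 1), paste(mid, collapse = ""), sample(SYNTH_END, 1))
}

#' Generate a synthetic multi-target activity dataset
#'
#' For each molecule, each target's motif is planted independently with
#' probability `active_fraction`; the emitted label is `active` iff the final
#' molecule contains the motif substructure (matched with SMARTS on the
#' assembled molecule, so accidental matches are labelled honestly), flipped
#' with probability `label_noise`. Potency values (`activity_um`) are drawn
#' consistently with the emitted label around the 10 uM rule. Because motifs
#' are planted independently, some molecules are active on several targets.
#'
#' @param spec An [synth_spec()].
#' @return List with `records` (long activity tibble in the same schema as
#'   [read_activity_data()]) and `registry` (an `epi_registry`). The records
#'   carry a `motif_match` attribute: the noise-free motif-presence matrix.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "epi_synth_spec"))
  set.seed(spec$seed)
  n <- spec$n_molecules
  target_ids <- names(spec$targets)
  k <- length(target_ids)

  plant <- matrix(runif(n * k) < spec$active_fraction, n, k,
                  dimnames = list(NULL, target_ids))
  smiles <- character(n)
  for (i in seq_len(n)) {
    motifs <- unlist(spec$targets[plant[i, ]])
    chunks <- vapply(motifs, function(m) SYNTH_MOTIFS[[m]]$chunk, character(1))
    # carbon spacer after each motif so adjacent motifs cannot interfere
    if (length(chunks) > 0) chunks <- paste0(chunks, "C")
    smiles[i] <- assemble_smiles(chunks, sample(1:3, 1))
  }
  compound_id <- sprintf("SYN%05d", seq_len(n))

  # honest labels: substructure match on the assembled molecule
  match_mat <- matrix(FALSE, n, k, dimnames = list(compound_id, target_ids))
  sdf <- synth_sdfset(smiles, compound_id)
  for (j in seq_len(k)) {
    motif <- SYNTH_MOTIFS[[spec$targets[[j]]]]
    hits <- ChemmineR::smartsSearchOB(sdf, motif$smarts, uniqueMatches = FALSE)
    match_mat[, j] <- hits > 0
  }

  flip <- matrix(runif(n * k) < spec$label_noise, n, k)
  label_mat <- xor(match_mat, flip)

  act_um <- matrix(0, n, k)
  act_um[label_mat] <- 10^runif(sum(label_mat), -3, 1)        # <= 10 uM
  act_um[!label_mat] <- 10^runif(sum(!label_mat), 1.01, 3)    # > 10 uM

  records <- tibble(
    compound_id = rep(compound_id, each = k),
    smiles = rep(smiles, each = k),
    target_id = rep(target_ids, times = n),
    activity_um = as.vector(t(act_um)),
    label = ifelse(as.vector(t(label_mat)), "active", "inactive")
  )
  registry <- target_registry(target_ids, unname(spec$object_groups[target_ids]))
  attr(records, "motif_match") <- match_mat
  list(records = records, registry = registry)
}

# SMILES vector -> SDFset (synthetic molecules always parse; error otherwise)
synth_sdfset <- function(smiles, ids) {
  smitext <- paste0(smiles, "\t", ids, "\n", collapse = "")
  sdftext <- ChemmineOB::convertFormat("SMI", "SDF", smitext)
  sdf <- suppressWarnings(
    ChemmineR::read.SDFset(ChemmineR::read.SDFstr(textConnection(sdftext)))
  )
  if (length(sdf) != length(smiles)) {
    abort("synthetic SMILES failed to parse; generator invariant violated")
  }
  sdf
}

#' Multilabel fixture with controlled target overlap and unknown labels
#'
#' Builds a dataset where a controllable fraction of molecules is active on
#' two or more targets (to exercise multi-target validation, which requires
#' compounds with at least two known active targets), and where a fraction of
#' (compound, target) labels is masked as `unknown` (which the validation
#' protocol must exclude from counting).
#'
#' Each molecule gets one primary motif with probability `active_fraction`;
#' with probability `overlap` a second (distinct) target's motif is added as
#' well, so `overlap = 0` yields no multi-target actives and `overlap = 1`
#' with two targets makes every active molecule active on both.
#'
#' @param n_targets Number of targets (2..5).
#' @param overlap Probability that an active molecule carries a second motif.
#' @param seed Integer seed.
#' @param n_molecules Number of compounds.
#' @param active_fraction Probability a molecule carries any motif.
#' @param unknown_fraction Fraction of labels masked as `unknown`.
#' @return As [generate_dataset()]: list with `records` and `registry`.
#' @export
make_multilabel_fixture <- function(n_targets = 5, overlap = 0.3, seed = 1,
                                    n_molecules = 300, active_fraction = 0.6,
                                    unknown_fraction = 0.2) {
  stopifnot(n_targets >= 2, n_targets <= length(SYNTH_MOTIFS),
            overlap >= 0, overlap <= 1,
            unknown_fraction >= 0, unknown_fraction < 1)
  set.seed(seed)
  target_ids <- paste0("T", seq_len(n_targets))
  motifs <- setNames(as.list(names(SYNTH_MOTIFS)[seq_len(n_targets)]), target_ids)

  plant <- matrix(FALSE, n_molecules, n_targets, dimnames = list(NULL, target_ids))
  for (i in seq_len(n_molecules)) {
    if (runif(1) < active_fraction) {
      first <- sample.int(n_targets, 1)
      plant[i, first] <- TRUE
      if (runif(1) < overlap) {
        others <- setdiff(seq_len(n_targets), first)
        plant[i, others[sample.int(length(others), 1)]] <- TRUE
      }
    }
  }
  compound_id <- sprintf("MLF%05d", seq_len(n_molecules))
  smiles <- character(n_molecules)
  for (i in seq_len(n_molecules)) {
    chunks <- vapply(unlist(motifs[plant[i, ]]),
                     function(m) SYNTH_MOTIFS[[m]]$chunk, character(1))
    if (length(chunks) > 0) chunks <- paste0(chunks, "C")
    smiles[i] <- assemble_smiles(chunks, sample(1:3, 1))
  }

  match_mat <- matrix(FALSE, n_molecules, n_targets,
                      dimnames = list(compound_id, target_ids))
  sdf <- synth_sdfset(smiles, compound_id)
  for (j in seq_len(n_targets)) {
    hits <- ChemmineR::smartsSearchOB(sdf, SYNTH_MOTIFS[[motifs[[j]]]]$smarts,
                                      uniqueMatches = FALSE)
    match_mat[, j] <- hits > 0
  }

  label <- ifelse(as.vector(t(match_mat)), "active", "inactive")
  mask <- runif(length(label)) < unknown_fraction
  # multi-target actives keep two active labels known, so masking cannot
  # silently empty the eligible set of the pooled validation protocol
  for (i in which(rowSums(match_mat) >= 2)) {
    act <- which(match_mat[i, ])
    protect <- (i - 1L) * n_targets + act[sample.int(length(act), 2)]
    mask[protect] <- FALSE
  }
  label[mask] <- "unknown"
  act_um <- rep(NA_real_, length(label))
  act_um[label == "active"] <- 10^runif(sum(label == "active"), -3, 1)
  act_um[label == "inactive"] <- 10^runif(sum(label == "inactive"), 1.01, 3)

  records <- tibble(
    compound_id = rep(compound_id, each = n_targets),
    smiles = rep(smiles, each = n_targets),
    target_id = rep(target_ids, times = n_molecules),
    activity_um = act_um,
    label = label
  )
  grp <- c("HDAC", "HMT", "HDM", "HAT", "DNMT")
  registry <- target_registry(target_ids, rep_len(grp, n_targets))
  attr(records, "motif_match") <- match_mat
  list(records = records, registry = registry)
}
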