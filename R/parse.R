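# SMILES parsing via OpenBabel (ChemmineOB) + ChemmineR block accessors.
# Returns plain R structures (atoms, bonds, charges, ring/aromatic perception)
# that the featurizer turns into molecular graphs.

DEFAULT_VALENCE <- c(C = 4, N = 3, O = 2, S = 2, F = 1, Cl = 1, Br = 1, I = 1,
                     P = 3, B = 3, Si = 4)

# Parse a vector of SMILES through OpenBabel. Returns a list of parsed
# molecules (NULL where parsing failed) with a "failures" attribute.
ob_parse_smiles <- function(smiles, ids = NULL) {
  stopifnot(is.character(smiles))
  n <- length(smiles)
  if (is.null(ids)) ids <- paste0("mol", seq_len(n))
  stopifnot(length(ids) == n, !anyDuplicated(ids))

  out <- vector("list", n)
  names(out) <- ids
  failures <- tibble(id = character(), smiles = character(), reason = character())

  ok <- !is.na(smiles) & nzchar(trimws(smiles))
  if (any(!ok)) {
    failures <- bind_rows(failures, tibble(
      id = ids[!ok], smiles = smiles[!ok], reason = "empty SMILES"
    ))
  }
  if (!any(ok)) {
    attr(out, "failures") <- failures
    return(out)
  }

  smitext <- paste0(smiles[ok], "\t", ids[ok], "\n", collapse = "")
  # -e: keep converting after an unparseable entry instead of aborting the batch
  sdftext <- ChemmineOB::convertFormat("SMI", "SDF", smitext,
                                       options = data.frame(names = "e", args = ""))
  recs <- strsplit(sdftext, "\\$\\$\\$\\$\n")[[1]]
  recs <- recs[nzchar(trimws(recs))]

  if (length(recs) > 0) {
    sdf <- suppressWarnings(
      ChemmineR::read.SDFset(ChemmineR::read.SDFstr(textConnection(sdftext)))
    )
    titles <- vapply(recs, function(r) {
      sub("\\s+$", "", strsplit(r, "\n", fixed = TRUE)[[1]][1])
    }, character(1), USE.NAMES = FALSE)
    for (j in seq_along(recs)) {
      id <- titles[j]
      if (!id %in% ids) next
      parsed <- tryCatch(
        parse_one_mol(sdf[[j]], recs[j]),
        error = function(e) structure(conditionMessage(e), class = "epi_parse_fail")
      )
      if (inherits(parsed, "epi_parse_fail")) {
        failures <- bind_rows(failures, tibble(
          id = id, smiles = smiles[match(id, ids)], reason = as.character(parsed)
        ))
      } else {
        parsed$smiles <- smiles[match(id, ids)]
        out[[id]] <- parsed
      }
    }
  }

  missing <- setdiff(ids[ok], c(names(out)[!vapply(out, is.null, logical(1))],
                                failures$id))
  if (length(missing) > 0) {
    failures <- bind_rows(failures, tibble(
      id = missing,
      smiles = smiles[match(missing, ids)],
      reason = "unparseable SMILES (rejected by OpenBabel)"
    ))
  }
  attr(out, "failures") <- failures
  out
}

# One ChemmineR SDF object + its raw molblock text -> parsed molecule.
parse_one_mol <- function(sdfobj, rawtext) {
  ab <- ChemmineR::atomblock(sdfobj)
  n_atoms <- nrow(ab)
  if (is.null(n_atoms) || n_atoms < 1) stop("molecule has no atoms")
  elements <- sub("_.*$", "", rownames(ab))

  bb <- tryCatch(ChemmineR::bondblock(sdfobj), error = function(e) NULL)
  bonds <- matrix(integer(0), ncol = 3)
  if (!is.null(bb) && nrow(bb) > 0 && ncol(bb) >= 3) {
    bm <- matrix(as.integer(as.matrix(bb[, 1:3, drop = FALSE])), ncol = 3)
    keep <- bm[, 1] >= 1 & bm[, 2] >= 1 & bm[, 1] <= n_atoms & bm[, 2] <= n_atoms
    bonds <- bm[keep, , drop = FALSE]
  }
  colnames(bonds) <- c("from", "to", "order")

  charges <- numeric(n_atoms)
  chg_lines <- grep("^M  CHG", strsplit(rawtext, "\n", fixed = TRUE)[[1]], value = TRUE)
  for (ln in chg_lines) {
    vals <- as.integer(strsplit(trimws(sub("^M  CHG\\s+\\d+", "", ln)), "\\s+")[[1]])
    if (length(vals) >= 2) {
      idx <- vals[seq(1, length(vals) - 1, by = 2)]
      chg <- vals[seq(2, length(vals), by = 2)]
      charges[idx] <- chg
    }
  }

  # largest-fragment selection for multi-fragment inputs (salts)
  n_fragments <- 1L
  if (n_atoms > 1) {
    g <- igraph::graph_from_edgelist(bonds[, 1:2, drop = FALSE], directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, n_atoms - igraph::vcount(g)))
    comp <- igraph::components(g)
    n_fragments <- comp$no
    if (comp$no > 1) {
      keep_comp <- which.max(comp$csize)
      keep_atoms <- which(comp$membership == keep_comp)
      remap <- match(seq_len(n_atoms), keep_atoms)
      keep_bonds <- bonds[, "from"] %in% keep_atoms & bonds[, "to"] %in% keep_atoms
      bonds <- bonds[keep_bonds, , drop = FALSE]
      bonds[, "from"] <- remap[bonds[, "from"]]
      bonds[, "to"] <- remap[bonds[, "to"]]
      elements <- elements[keep_atoms]
      charges <- charges[keep_atoms]
      n_atoms <- length(keep_atoms)
    }
  }

  # ring perception + aromaticity (on the kept fragment only)
  aromatic_atoms <- logical(n_atoms)
  ring_atoms <- logical(n_atoms)
  n_bonds <- nrow(bonds)
  ring_bonds <- logical(n_bonds)
  aromatic_bonds <- logical(n_bonds)
  if (n_bonds >= 3) {
    rg <- tryCatch(
      suppressWarnings(ChemmineR::rings(sdfobj, upper = 10, type = "all", arom = TRUE)),
      error = function(e) list(RINGS = list(), AROMATIC = logical(0))
    )
    ring_sets <- lapply(rg$RINGS, function(r) as.integer(sub("^.*_", "", r)))
    arom_flags <- rg$AROMATIC
    # rings() ran on the full molecule; map indices onto the kept fragment
    if (exists("remap", inherits = FALSE) && n_fragments > 1) {
      ring_sets <- lapply(ring_sets, function(r) {
        r2 <- remap[r]
        if (anyNA(r2)) integer(0) else r2
      })
    }
    for (i in seq_along(ring_sets)) {
      rs <- ring_sets[[i]]
      if (length(rs) == 0) next
      ring_atoms[rs] <- TRUE
      if (isTRUE(arom_flags[i])) aromatic_atoms[rs] <- TRUE
      in_this <- bonds[, "from"] %in% rs & bonds[, "to"] %in% rs
      ring_bonds[in_this] <- TRUE
      if (isTRUE(arom_flags[i])) aromatic_bonds[in_this] <- TRUE
    }
  }

  degree <- tabulate(c(bonds[, "from"], bonds[, "to"]), nbins = n_atoms)

  # bond-order sums for implicit-H and hybridization assignment
  order_sum <- numeric(n_atoms)
  n_double <- integer(n_atoms)
  n_triple <- integer(n_atoms)
  if (n_bonds > 0) {
    for (b in seq_len(n_bonds)) {
      u <- bonds[b, "from"]; v <- bonds[b, "to"]; o <- bonds[b, "order"]
      order_sum[u] <- order_sum[u] + o
      order_sum[v] <- order_sum[v] + o
      if (o == 2) { n_double[u] <- n_double[u] + 1L; n_double[v] <- n_double[v] + 1L }
      if (o == 3) { n_triple[u] <- n_triple[u] + 1L; n_triple[v] <- n_triple[v] + 1L }
    }
  }

  base_val <- unname(DEFAULT_VALENCE[elements])
  base_val[is.na(base_val)] <- 0
  allowed <- base_val + ifelse(elements %in% c("N", "P"), charges,
                        ifelse(elements %in% c("O", "S"), charges, 0))
  # hypervalent S/P (sulfone, phosphate): valence expands to the bonded order
  allowed <- pmax(allowed, ifelse(elements %in% c("S", "P"), order_sum, 0))
  implicit_h <- pmax(0L, as.integer(round(allowed - order_sum)))

  hyb <- rep("sp3", n_atoms)
  hyb[n_double >= 1 | aromatic_atoms] <- "sp2"
  hyb[n_triple >= 1 | n_double >= 2] <- "sp"
  hyb[elements %in% c("F", "Cl", "Br", "I")] <- "other"

  list(
    n_atoms = n_atoms,
    elements = elements,
    bonds = bonds,
    charges = charges,
    degree = degree,
    implicit_h = implicit_h,
    aromatic_atoms = aromatic_atoms,
    aromatic_bonds = aromatic_bonds,
    ring_atoms = ring_atoms,
    ring_bonds = ring_bonds,
    hybridization = hyb,
    n_fragments = n_fragments
  )
}
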