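#' Convert SMILES strings to quantized molecular graphs
#'
#' Parses SMILES with OpenBabel and builds the graph representation consumed by
#' the neural encoders: per-atom and per-bond feature matrices plus a
#' directed-edge incidence structure (two directed edges per chemical bond,
#' with a reverse-edge index). Hydrogens stay implicit (a count feature, not a
#' node). Multi-fragment inputs (salts) keep the largest fragment.
#'
#' @param smiles A character vector of SMILES strings.
#' @param scheme A [feature_scheme()].
#' @param ids Optional unique identifiers (default `mol1..moln`).
#' @return For `smiles_to_graphs()`, a named list of `epi_molgraph` objects
#'   (`NULL` where parsing failed) with a `failures` attribute — a tibble of
#'   offending inputs; parse failures are recorded, never silently dropped.
#'   For `smiles_to_graph()`, a single `epi_molgraph` (parse failure is an
#'   error naming the string).
#'
#' An `epi_molgraph` is a list with elements `n_atoms`, `atom_features`
#' (`n_atoms x atom_dim`), `n_bonds`, `bond_features` (`n_bonds x bond_dim`),
#' `directed_edges` (`2*n_bonds x 2` matrix of from/to atom indices; edges
#' `2k-1` and `2k` are the two directions of bond `k`), `reverse_index`
#' (involution pairing each directed edge with its reverse), `bond_of_edge`,
#' and `atom_incoming` (for each atom, the directed edges pointing to it).
#' @examples
#' g <- smiles_to_graph("CCO")
#' g$n_atoms           # 3 heavy atoms
#' g$reverse_index     # 2 1 4 3
#' @export
smiles_to_graphs <- function(smiles, scheme = feature_scheme(), ids = NULL) {
  parsed <- ob_parse_smiles(smiles, ids)
  out <- lapply(parsed, function(p) {
    if (is.null(p)) NULL else build_molgraph(p, scheme)
  })
  attr(out, "failures") <- attr(parsed, "failures")
  attr(out, "scheme_fingerprint") <- scheme$fingerprint
  out
}

#' @rdname smiles_to_graphs
#' @export
smiles_to_graph <- function(smiles, scheme = feature_scheme()) {
  stopifnot(is.character(smiles), length(smiles) == 1)
  gs <- smiles_to_graphs(smiles, scheme)
  if (is.null(gs[[1]])) {
    abort(paste0("SMILES could not be parsed: '", smiles, "' (",
                 attr(gs, "failures")$reason[1], ")"))
  }
  gs[[1]]
}

build_molgraph <- function(p, scheme) {
  n_atoms <- p$n_atoms
  n_bonds <- nrow(p$bonds)

  af <- matrix(0, n_atoms, scheme$atom_dim)
  for (i in seq_len(n_atoms)) {
    af[i, ] <- atom_feature_vector(
      scheme, p$elements[i], p$degree[i], p$charges[i], p$implicit_h[i],
      p$aromatic_atoms[i], p$hybridization[i], p$ring_atoms[i]
    )
  }

  bf <- matrix(0, n_bonds, scheme$bond_dim)
  sp_like <- p$hybridization %in% c("sp", "sp2")
  if (n_bonds > 0) {
    for (b in seq_len(n_bonds)) {
      u <- p$bonds[b, "from"]; v <- p$bonds[b, "to"]
      conj <- p$aromatic_bonds[b] || (sp_like[u] && sp_like[v])
      bf[b, ] <- bond_feature_vector(scheme, p$bonds[b, "order"],
                                     p$aromatic_bonds[b], conj, p$ring_bonds[b])
    }
  }

  n_edges <- 2L * n_bonds
  de <- matrix(0L, n_edges, 2, dimnames = list(NULL, c("from", "to")))
  if (n_bonds > 0) {
    de[seq(1, n_edges, by = 2), ] <- p$bonds[, 1:2, drop = FALSE]
    de[seq(2, n_edges, by = 2), ] <- p$bonds[, 2:1, drop = FALSE]
  }
  rev_idx <- if (n_edges > 0) as.integer(seq_len(n_edges) + c(1L, -1L)) else integer(0)
  bond_of_edge <- if (n_edges > 0) rep(seq_len(n_bonds), each = 2L) else integer(0)
  atom_incoming <- incoming_by_atom(de, n_atoms)

  structure(list(
    n_atoms = n_atoms,
    atom_features = af,
    n_bonds = n_bonds,
    bond_features = bf,
    directed_edges = de,
    reverse_index = rev_idx,
    bond_of_edge = bond_of_edge,
    atom_incoming = atom_incoming,
    elements = p$elements,
    aromatic_atoms = p$aromatic_atoms,
    smiles = p$smiles,
    n_fragments = p$n_fragments,
    scheme_fingerprint = scheme$fingerprint
  ), class = "epi_molgraph")
}

#' @method print epi_molgraph
#' @export
print.epi_molgraph <- function(x, ...) {
  cat("<epi_molgraph>", x$n_atoms, "atoms,", x$n_bonds, "bonds |",
      if (!is.null(x$smiles)) x$smiles else "", "\n")
  invisible(x)
}

#' Validate the structural invariants of a molecular graph
#'
#' Checks that the directed-edge structure is consistent: two directed edges
#' per bond, the reverse index is a fixed-point-free involution, and every
#' directed edge appears exactly once in its head atom's incoming list.
#'
#' @param graph An `epi_molgraph`.
#' @return `TRUE` invisibly; aborts with a message on violation.
#' @export
validate_molgraph <- function(graph) {
  stopifnot(inherits(graph, "epi_molgraph"))
  n_edges <- nrow(graph$directed_edges)
  if (n_edges != 2L * graph$n_bonds) abort("directed edge count != 2 * n_bonds")
  if (n_edges > 0) {
    r <- graph$reverse_index
    if (any(r[r] != seq_len(n_edges))) abort("reverse_index is not an involution")
    if (any(r == seq_len(n_edges))) abort("reverse_index has fixed points")
    flip <- graph$directed_edges[r, c(2, 1), drop = FALSE]
    if (!all(flip == graph$directed_edges)) abort("reverse edge does not flip endpoints")
  }
  inc <- unlist(graph$atom_incoming)
  if (length(inc) != n_edges || anyDuplicated(inc) > 0) {
    abort("atom_incoming does not partition the directed edges")
  }
  for (v in seq_len(graph$n_atoms)) {
    e <- graph$atom_incoming[[v]]
    if (length(e) > 0 && any(graph$directed_edges[e, "to"] != v)) {
      abort("atom_incoming lists an edge with the wrong head")
    }
  }
  invisible(TRUE)
}

#' Relabel the atoms of a molecular graph
#'
#' Applies a permutation to atom indices, producing the graph that would be
#' obtained from a SMILES spelling that visits atoms in a different order.
#' Used to test the permutation invariance of molecule embeddings.
#'
#' @param graph An `epi_molgraph`.
#' @param perm An integer permutation of `1:n_atoms`; `perm[i]` is the new
#'   index of old atom `i`.
#' @return A relabelled `epi_molgraph`.
#' @export
permute_molgraph <- function(graph, perm) {
  stopifnot(inherits(graph, "epi_molgraph"),
            length(perm) == graph$n_atoms,
            all(sort(perm) == seq_len(graph$n_atoms)))
  g <- graph
  inv <- order(perm)
  g$atom_features <- graph$atom_features[inv, , drop = FALSE]
  g$elements <- graph$elements[inv]
  g$aromatic_atoms <- graph$aromatic_atoms[inv]
  de <- graph$directed_edges
  de[, "from"] <- perm[de[, "from"]]
  de[, "to"] <- perm[de[, "to"]]
  g$directed_edges <- de
  g$atom_incoming <- incoming_by_atom(de, g$n_atoms)
  g$smiles <- NULL
  g
}

incoming_by_atom <- function(de, n_atoms) {
  inc <- rep(list(integer(0)), n_atoms)
  if (nrow(de) > 0) {
    grp <- split(seq_len(nrow(de)), de[, "to"])
    inc[as.integer(names(grp))] <- grp
  }
  inc
}
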