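# Disjoint-union batching of molecular graphs. A batch of molecules is one
# large graph with block-diagonal structure; message passing is performed
# with gather + rowsum() aggregations over precomputed index vectors:
#   efrom/eto     tail and head atom of each directed edge
#   (ei, ki)      pairs with head(ki) == tail(ei) and ki != reverse(ei)
#                 (the directed-bond incidence used by the DMPNN)
#   mol_of_atom   readout grouping
graph_batch <- function(graphs) {
  stopifnot(length(graphs) >= 1)
  if (any(vapply(graphs, is.null, logical(1)))) {
    abort("graph_batch: NULL graph in batch (unparsed molecule)")
  }
  n_atoms <- vapply(graphs, function(g) g$n_atoms, integer(1))
  n_edges <- vapply(graphs, function(g) 2L * g$n_bonds, integer(1))
  atom_off <- cumsum(c(0L, n_atoms[-length(n_atoms)]))
  edge_off <- cumsum(c(0L, n_edges[-length(n_edges)]))
  N <- sum(n_atoms); E <- sum(n_edges); M <- length(graphs)

  X <- do.call(rbind, lapply(graphs, function(g) g$atom_features))
  BF <- do.call(rbind, lapply(graphs, function(g) g$bond_features))

  efrom <- integer(E); eto <- integer(E); erev <- integer(E); ebond_row <- integer(E)
  bf_off <- cumsum(c(0L, vapply(graphs, function(g) g$n_bonds, integer(1))))
  for (i in seq_along(graphs)) {
    g <- graphs[[i]]
    if (g$n_bonds == 0) next
    idx <- edge_off[i] + seq_len(2L * g$n_bonds)
    efrom[idx] <- g$directed_edges[, "from"] + atom_off[i]
    eto[idx] <- g$directed_edges[, "to"] + atom_off[i]
    erev[idx] <- g$reverse_index + edge_off[i]
    ebond_row[idx] <- g$bond_of_edge + bf_off[i]
  }

  if (E > 0) {
    # (ei, ki) pairs: incoming edges ki grouped by head atom, expanded per
    # outgoing edge ei with matching tail, minus the reverse pair
    kcnt <- tabulate(eto, N)
    ks <- order(eto)
    k_start <- cumsum(c(0L, kcnt))
    nk <- kcnt[efrom]
    ei <- rep.int(seq_len(E), nk)
    ki <- ks[sequence(nk) + rep.int(k_start[efrom], nk)]
    keep <- ki != erev[ei]
    ei <- ei[keep]; ki <- ki[keep]
    FE <- cbind(X[efrom, , drop = FALSE], BF[ebond_row, , drop = FALSE])
  } else {
    ei <- integer(0); ki <- integer(0)
    FE <- matrix(0, 0, ncol(X) + ncol(BF))
  }

  list(X = X, FE = FE,
       efrom = efrom, eto = eto, erev = erev, ei = ei, ki = ki,
       mol_of_atom = rep(seq_len(M), n_atoms),
       n_mols = M, n_atoms_total = N, n_edges_total = E,
       sizes = n_atoms)
}

# sum rows of M gathered at `gather` into `ngroups` bins keyed by `groups`
# (rows of the result are zero where a group never occurs)
agg_rows <- function(M, gather, groups, ngroups) {
  agg_rows_cpp(M, if (is.null(gather)) integer(0) else gather, groups, ngroups)
}

# neighborhood message: (A H)[v, ] = sum over edges u->v of H[u, ]
msg_atoms <- function(batch, H) {
  agg_rows(H, batch$efrom, batch$eto, batch$n_atoms_total)
}
# transpose counterpart: (A' D)[u, ] = sum over edges u->v of D[v, ]
msg_atoms_t <- function(batch, D) {
  agg_rows(D, batch$eto, batch$efrom, batch$n_atoms_total)
}
# directed-bond message: sum of incoming edge states excluding the reverse
msg_edges <- function(batch, He) {
  agg_rows(He, batch$ki, batch$ei, batch$n_edges_total)
}
msg_edges_t <- function(batch, D) {
  agg_rows(D, batch$ei, batch$ki, batch$n_edges_total)
}
# per-atom aggregation of incoming edge states
edges_to_atoms <- function(batch, He) {
  agg_rows(He, NULL, batch$eto, batch$n_atoms_total)
}
edges_to_atoms_t <- function(batch, D) {
  D[batch$eto, , drop = FALSE]
}
# readout: sum (or mean) of atom states per molecule, and its transpose
readout_fwd <- function(batch, H, mode) {
  Z <- rowsum(H, batch$mol_of_atom)
  if (mode == "mean") Z <- Z / batch$sizes
  Z
}
readout_bwd <- function(batch, dZ, mode) {
  if (mode == "mean") dZ <- dZ / batch$sizes
  dZ[batch$mol_of_atom, , drop = FALSE]
}

#' Aggregate per-atom hidden states into a molecule embedding
#'
#' Order-invariant pooling of node states: the molecule vector is the sum (or
#' mean) of its atoms' hidden states.
#'
#' @param states Numeric matrix `n_atoms x hidden_dim` of per-atom states.
#' @param mode `"sum"` or `"mean"`.
#' @return A numeric vector of length `hidden_dim`.
#' @export
readout <- function(states, mode = c("sum", "mean")) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(states), nrow(states) >= 1)
  if (mode == "sum") colSums(states) else colSums(states) / nrow(states)
}
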