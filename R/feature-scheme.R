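#' Atom/bond featurization scheme for molecular graphs
#'
#' Defines how heavy atoms and bonds are turned into fixed-length numeric
#' feature vectors when a SMILES string is quantized into a molecular graph.
#' Atoms get a one-hot element type over a declared vocabulary plus degree,
#' formal charge, implicit hydrogen count, an aromaticity flag, a hybridization
#' one-hot and a ring-membership flag. Bonds get a one-hot bond order (single,
#' double, triple, aromatic) plus conjugation and ring flags. Hydrogens are
#' implicit: they contribute a count feature and are never materialized as
#' graph nodes.
#'
#' @param elements Character vector of element symbols given dedicated one-hot
#'   slots; anything else falls into a shared "other" slot.
#' @param max_degree Degrees `0..max_degree` get one-hot slots (higher degrees
#'   saturate at the last slot).
#' @param max_implicit_h Implicit H counts `0..max_implicit_h`, saturating.
#' @return An object of class `epi_feature_scheme` with the per-atom dimension
#'   `atom_dim` and per-bond dimension `bond_dim`.
#' @examples
#' sc <- feature_scheme()
#' sc$atom_dim
#' @export
feature_scheme <- function(elements = c("C", "N", "O", "S", "F", "Cl", "Br", "I", "P"),
                           max_degree = 5L,
                           max_implicit_h = 4L) {
  stopifnot(length(elements) >= 1, max_degree >= 1, max_implicit_h >= 1)
  hyb_levels <- c("sp", "sp2", "sp3", "other")
  atom_dim <- (length(elements) + 1L) +  # element one-hot + other
    (max_degree + 1L) +                  # degree one-hot 0..max
    1L +                                 # formal charge (scalar)
    (max_implicit_h + 1L) +              # implicit H one-hot 0..max
    1L +                                 # aromatic flag
    length(hyb_levels) +                 # hybridization one-hot
    1L                                   # ring membership flag
  bond_dim <- 4L + 1L + 1L               # order one-hot + conjugation + ring
  out <- list(
    elements = elements,
    max_degree = as.integer(max_degree),
    max_implicit_h = as.integer(max_implicit_h),
    hyb_levels = hyb_levels,
    atom_dim = as.integer(atom_dim),
    bond_dim = as.integer(bond_dim)
  )
  out$fingerprint <- rlang::hash(out[c("elements", "max_degree", "max_implicit_h", "hyb_levels")])
  structure(out, class = "epi_feature_scheme")
}

#' @method print epi_feature_scheme
#' @export
print.epi_feature_scheme <- function(x, ...) {
  cat("<epi_feature_scheme> atom_dim =", x$atom_dim,
      "| bond_dim =", x$bond_dim,
      "| elements:", paste(x$elements, collapse = " "), "+ other\n")
  invisible(x)
}

one_hot <- function(idx, n) {
  v <- numeric(n)
  v[idx] <- 1
  v
}

# atom feature vector from parsed atom properties
atom_feature_vector <- function(scheme, element, degree, charge, n_implicit_h,
                                aromatic, hybridization, in_ring) {
  el_idx <- match(element, scheme$elements)
  if (is.na(el_idx)) el_idx <- length(scheme$elements) + 1L
  deg_idx <- min(degree, scheme$max_degree) + 1L
  h_idx <- min(n_implicit_h, scheme$max_implicit_h) + 1L
  hyb_idx <- match(hybridization, scheme$hyb_levels)
  if (is.na(hyb_idx)) hyb_idx <- length(scheme$hyb_levels)
  c(one_hot(el_idx, length(scheme$elements) + 1L),
    one_hot(deg_idx, scheme$max_degree + 1L),
    charge,
    one_hot(h_idx, scheme$max_implicit_h + 1L),
    as.numeric(aromatic),
    one_hot(hyb_idx, length(scheme$hyb_levels)),
    as.numeric(in_ring))
}

bond_feature_vector <- function(scheme, order, aromatic, conjugated, in_ring) {
  ord_idx <- if (aromatic) 4L else min(order, 3L)
  c(one_hot(ord_idx, 4L), as.numeric(conjugated), as.numeric(in_ring))
}
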