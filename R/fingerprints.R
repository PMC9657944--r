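#' Morgan (ECFP-style) circular fingerprints
#'
#' Folded circular substructure fingerprints computed by OpenBabel's ECFP
#' implementation (via the `obabel` command-line tool), used as the classical
#' baseline featurizer against the learned graph embeddings. Radius 2 with
#' 2048 bits corresponds to the standard ECFP4 setting. OpenBabel produces
#' 4096-bit vectors natively; smaller widths are obtained by OR-folding,
#' which preserves determinism and invariance to atom ordering.
#'
#' @param smiles Character vector of SMILES.
#' @param radius Circular neighborhood radius (0, 1, 2, 3 -> ECFP0/2/4/6).
#' @param n_bits Folded width; a power of two, at most 4096.
#' @return A binary matrix `length(smiles) x n_bits`, row order matching the
#'   input, suitable as a feature matrix for [train_booster()].
#' @examples
#' fp <- morgan_fingerprint(c("CCO", "OCC"))
#' identical(fp[1, ], fp[2, ])  # same molecule, same bits
#' @export
morgan_fingerprint <- function(smiles, radius = 2, n_bits = 2048) {
  stopifnot(is.character(smiles), length(smiles) >= 1,
            radius %in% 0:5, n_bits >= 2, n_bits <= 4096,
            bitwAnd(as.integer(n_bits), as.integer(n_bits) - 1L) == 0L)
  ids <- paste0("m", seq_along(smiles))
  smi_file <- tempfile(fileext = ".smi")
  on.exit(unlink(smi_file), add = TRUE)
  writeLines(paste(smiles, ids), smi_file)
  out <- suppressWarnings(system2(
    "obabel", c(smi_file, "-ofpt", paste0("-xf", "ECFP", 2 * radius), "-xh"),
    stdout = TRUE, stderr = FALSE
  ))

  headers <- grep("^>", out)
  got <- sub("^>(\\S+).*$", "\\1", out[headers])
  missing <- setdiff(ids, got)
  if (length(missing) > 0) {
    abort(paste0("unparseable SMILES: ",
                 paste(utils::head(smiles[match(missing, ids)], 5), collapse = ", ")))
  }

  # hex dump -> 4096-bit rows (nibble lookup, fixed reading order)
  nibble <- matrix(0, 16, 4)
  for (v in 0:15) nibble[v + 1, ] <- as.integer(intToBits(v))[4:1]
  rownames(nibble) <- c(0:9, letters[1:6])

  blocks <- split(seq_along(out), cumsum(seq_along(out) %in% headers))
  blocks <- blocks[vapply(blocks, function(ix) ix[1] %in% headers, logical(1))]
  fp <- matrix(0, length(smiles), 4096)
  for (j in seq_along(blocks)) {
    lines <- out[blocks[[j]][-1]]
    lines <- grep("^[0-9a-fA-F ]+$", lines, value = TRUE)  # drop info lines
    hex <- gsub("\\s+", "", paste(lines, collapse = ""))
    nb <- strsplit(tolower(hex), "")[[1]]
    bits <- as.vector(t(nibble[nb, , drop = FALSE]))
    if (length(bits) != 4096) {
      abort("unexpected fingerprint width from obabel")
    }
    fp[match(got[j], ids), ] <- bits
  }

  # OR-fold 4096 -> n_bits
  while (ncol(fp) > n_bits) {
    half <- ncol(fp) / 2
    fp <- pmin(fp[, 1:half, drop = FALSE] + fp[, (half + 1):(2 * half), drop = FALSE], 1)
  }
  storage.mode(fp) <- "double"
  fp
}
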