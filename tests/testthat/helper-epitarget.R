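# Shared fixtures, built once per test run.

# small noise-free single-target dataset (amide motif on T1)
small_dataset <- local({
  memo <- NULL
  function() {
    if (is.null(memo)) {
      ds <- generate_dataset(synth_spec(n_molecules = 120, label_noise = 0, seed = 404))
      memo <<- ds
    }
    memo
  }
})

small_target_data <- function(target = "T1") {
  dplyr::filter(small_dataset()$records, target_id == target)
}

# parsed graphs for the small dataset, cached
small_graphs <- local({
  memo <- NULL
  function(target = "T1") {
    if (is.null(memo)) {
      d <- small_target_data(target)
      memo <<- smiles_to_graphs(d$smiles, ids = paste0("r", seq_len(nrow(d))))
    }
    memo
  }
})

# quick low-capacity encoder config for unit tests
tiny_encoder <- function(kind = "gcn", seed = 1, epochs = 5, ...) {
  encoder_config(kind, hidden_dim = 16, depth = 2, epochs = epochs, seed = seed, ...)
}

# run a short python snippet (used only as an independent oracle)
run_python <- function(code) {
  f <- tempfile(fileext = ".py")
  writeLines(code, f)
  out <- suppressWarnings(system2("python", f, stdout = TRUE, stderr = FALSE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) stop("python oracle failed")
  out
}

# hand-rolled per-edge recursion implementing the directed-bond update with
# the incoming-minus-reverse rule; the independent oracle for the DMPNN
dmpnn_oracle <- function(graph, params, depth) {
  E <- nrow(graph$directed_edges)
  d <- ncol(params$Wm)
  relu0 <- function(x) pmax(x, 0)
  FE <- cbind(graph$atom_features[graph$directed_edges[, "from"], , drop = FALSE],
              graph$bond_features[graph$bond_of_edge, , drop = FALSE])
  h0 <- t(apply(FE, 1, function(f) relu0(drop(f %*% params$Wi) + params$bi)))
  if (E == 1) h0 <- matrix(h0, 1)
  h <- h0
  for (t in seq_len(depth)) {
    hn <- matrix(0, E, d)
    for (e in seq_len(E)) {
      u <- graph$directed_edges[e, "from"]
      m <- numeric(d)
      for (k in seq_len(E)) {
        if (graph$directed_edges[k, "to"] == u && k != graph$reverse_index[e]) {
          m <- m + h[k, ]
        }
      }
      hn[e, ] <- relu0(h0[e, ] + drop(m %*% params$Wm))
    }
    h <- hn
  }
  atom <- matrix(0, graph$n_atoms, d)
  for (v in seq_len(graph$n_atoms)) {
    m <- numeric(d)
    for (e in graph$atom_incoming[[v]]) m <- m + h[e, ]
    atom[v, ] <- relu0(drop(c(graph$atom_features[v, ], m) %*% params$Wa) + params$ba)
  }
  list(edge_states = h, atom_states = atom)
}

# bias broadcast mirroring the encoders' internal add_bias
add_bias_like <- function(M, b) M + matrix(b, nrow(M), length(b), byrow = TRUE)

# brute-force upper-tail hypergeometric by enumerating all C(N, n) draws
hyper_tail_bruteforce <- function(N, K, n, k) {
  if (n == 0) return(as.numeric(k == 0))
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)   # successes are items 1..K
  mean(hits >= k)
}
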