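#' Configuration for a molecular graph encoder
#'
#' @param kind Encoder architecture: `"dmpnn"` (directed-bond message
#'   passing), `"gcn"` (graph convolution), or `"ggnn"` (gated recurrent
#'   update).
#' @param hidden_dim Hidden state width and embedding dimension.
#' @param depth Number of message-passing steps `T` (an atom's receptive field
#'   is its `T`-bond neighborhood).
#' @param readout Pooling of atom states into the molecule vector.
#' @param dropout Dropout probability on hidden states during training
#'   (`0 <= dropout < 1`).
#' @param epochs Number of full passes over the training set.
#' @param learning_rate Adam step size.
#' @param batch_size Molecules per minibatch.
#' @param seed Integer seed controlling initialization and batch order;
#'   training is bitwise reproducible given the seed.
#' @return An `epi_encoder_config`.
#' @export
encoder_config <- function(kind = c("dmpnn", "gcn", "ggnn"), hidden_dim = 128,
                           depth = 3, readout = c("sum", "mean"), dropout = 0,
                           epochs = 30, learning_rate = 1e-3, batch_size = 50,
                           seed = 1) {
  kind <- match.arg(kind)
  readout <- match.arg(readout)
  stopifnot(hidden_dim >= 1, depth >= 1, dropout >= 0, dropout < 1,
            epochs >= 1, learning_rate > 0, batch_size >= 1)
  structure(list(kind = kind, hidden_dim = as.integer(hidden_dim),
                 depth = as.integer(depth), readout = readout,
                 dropout = dropout, epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "epi_encoder_config")
}

#' Initialize encoder parameters
#'
#' Glorot-uniform weight matrices for the architecture selected in `config`.
#' Exposed so that propagation mechanics can be examined with pinned weights.
#'
#' @param config An [encoder_config()].
#' @param scheme A [feature_scheme()].
#' @return A named list of weight matrices and bias vectors.
#' @export
init_encoder_params <- function(config, scheme = feature_scheme()) {
  switch(config$kind,
    gcn = init_gcn_params(scheme$atom_dim, config$hidden_dim, config$depth),
    ggnn = init_ggnn_params(scheme$atom_dim, config$hidden_dim, config$depth),
    dmpnn = init_dmpnn_params(scheme$atom_dim, scheme$bond_dim, config$hidden_dim)
  )
}

#' Run message passing over a single molecular graph
#'
#' These expose the propagation mechanics of the three encoders for a single
#' molecule with explicit parameters: `propagate_gcn()` and `propagate_ggnn()`
#' return the per-atom hidden states after `depth` steps; `propagate_dmpnn()`
#' returns both the per-directed-edge states and the per-atom states formed by
#' aggregating incoming edge states with the atom's own features.
#'
#' @param graph An `epi_molgraph`.
#' @param params Parameter list shaped like [init_encoder_params()].
#' @param depth Number of message-passing steps.
#' @return A matrix of per-atom states (GCN/GGNN), or for the DMPNN a list
#'   with `edge_states` and `atom_states`.
#' @export
propagate_gcn <- function(graph, params, depth) {
  if (graph$n_atoms == 0) abort("graph has no atoms")
  b <- graph_batch(list(graph))
  forward_gcn(b, params, depth, "sum")$H
}

#' @rdname propagate_gcn
#' @export
propagate_ggnn <- function(graph, params, depth) {
  if (graph$n_atoms == 0) abort("graph has no atoms")
  b <- graph_batch(list(graph))
  forward_ggnn(b, params, depth, "sum")$H
}

#' @rdname propagate_gcn
#' @export
propagate_dmpnn <- function(graph, params, depth) {
  if (graph$n_atoms == 0) abort("graph has no atoms")
  b <- graph_batch(list(graph))
  fwd <- forward_dmpnn(b, params, depth, "sum")
  list(edge_states = fwd$He, atom_states = fwd$H)
}

encoder_forward <- function(kind, batch, params, depth, readout_mode,
                            dropout = 0, training = FALSE) {
  switch(kind,
    gcn = forward_gcn(batch, params, depth, readout_mode, dropout, training),
    ggnn = forward_ggnn(batch, params, depth, readout_mode, dropout, training),
    dmpnn = forward_dmpnn(batch, params, depth, readout_mode, dropout, training)
  )
}

encoder_backward <- function(kind, batch, params, fwd, dlogits) {
  switch(kind,
    gcn = backward_gcn(batch, params, fwd, dlogits),
    ggnn = backward_ggnn(batch, params, fwd, dlogits),
    dmpnn = backward_dmpnn(batch, params, fwd, dlogits)
  )
}

#' Train a molecular encoder against binary activity labels
#'
#' Trains the selected graph neural network end-to-end with a logistic
#' classification head under binary cross-entropy, optimized with Adam. The
#' trained model keeps the head, but feature extraction ([embed()]) returns
#' the penultimate vector — the molecule embedding before the logistic head.
#'
#' @param data A data frame with columns `smiles` and `label`
#'   (`active`/`inactive`), one row per molecule, for a single target.
#' @param config An [encoder_config()].
#' @param scheme A [feature_scheme()].
#' @param graphs Optional pre-built list of `epi_molgraph` aligned with
#'   `data$smiles` (avoids re-parsing when training many models on one set).
#' @return An `epi_encoder` model object with elements `config`, `params`,
#'   `feature_dim`, and `loss_history` (mean training BCE per epoch).
#' @export
train_encoder <- function(data, config = encoder_config(),
                          scheme = feature_scheme(), graphs = NULL) {
  stopifnot(inherits(config, "epi_encoder_config"))
  data <- as_tibble(data)
  stopifnot(all(c("smiles", "label") %in% names(data)))
  y <- as.integer(data$label == "active")
  if (!all(data$label %in% c("active", "inactive"))) {
    abort("labels must be binary active/inactive for encoder training")
  }
  if (length(unique(y)) < 2) abort("encoder training needs both classes present")

  if (is.null(graphs)) {
    graphs <- smiles_to_graphs(data$smiles, scheme,
                               ids = paste0("r", seq_len(nrow(data))))
    fails <- attr(graphs, "failures")
    if (nrow(fails) > 0) {
      abort(paste0("unparseable SMILES in training data: ",
                   paste(utils::head(fails$smiles, 5), collapse = ", ")))
    }
  }
  stopifnot(length(graphs) == nrow(data))

  set.seed(config$seed)
  params <- init_encoder_params(config, scheme)
  opt <- adam_init(params)

  n <- nrow(data)
  ord <- sample.int(n)
  starts <- seq(1, n, by = config$batch_size)
  batch_idx <- lapply(starts, function(s) ord[s:min(s + config$batch_size - 1L, n)])
  batches <- lapply(batch_idx, function(ix) {
    list(b = graph_batch(graphs[ix]), y = y[ix])
  })

  loss_history <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    ep_losses <- numeric(length(batches))
    for (bi in sample.int(length(batches))) {
      bt <- batches[[bi]]
      fwd <- encoder_forward(config$kind, bt$b, params, config$depth,
                             config$readout, config$dropout, training = TRUE)
      l <- bce_with_logits(fwd$logits, bt$y)
      if (!is.finite(l$loss)) {
        abort(paste0("non-finite training loss at epoch ", ep,
                     " (learning_rate = ", config$learning_rate, ")"))
      }
      ep_losses[bi] <- l$loss
      grads <- encoder_backward(config$kind, bt$b, params, fwd, l$dlogits)
      upd <- adam_step(params, grads, opt, config$learning_rate)
      params <- upd$params; opt <- upd$state
    }
    loss_history[ep] <- mean(ep_losses)
  }

  structure(list(
    config = config,
    scheme = scheme,
    params = params,
    feature_dim = config$hidden_dim,
    loss_history = loss_history,
    n_train = n,
    class_balance = mean(y)
  ), class = "epi_encoder")
}

#' @method print epi_encoder
#' @export
print.epi_encoder <- function(x, ...) {
  cat("<epi_encoder>", toupper(x$config$kind),
      "| hidden", x$config$hidden_dim, "| depth", x$config$depth,
      "| trained on", x$n_train, "molecules",
      sprintf("(%.0f%% active)", 100 * x$class_balance),
      "| final loss", sprintf("%.4f", utils::tail(x$loss_history, 1)), "\n")
  invisible(x)
}

#' Extract molecule embeddings from a trained encoder
#'
#' Deterministic inference-mode forward pass (dropout off); returns the
#' penultimate molecule representation used as features by the boosted
#' classifier. Row order matches input order, and values do not depend on how
#' molecules are grouped into batches.
#'
#' @param model A trained `epi_encoder`.
#' @param graphs A list of `epi_molgraph`, or a character vector of SMILES.
#' @param head If `TRUE`, also return the head probability as an attribute.
#' @return Numeric matrix `n x feature_dim`.
#' @export
embed <- function(model, graphs, head = FALSE) {
  stopifnot(inherits(model, "epi_encoder"))
  if (is.character(graphs)) {
    graphs <- smiles_to_graphs(graphs, model$scheme)
    fails <- attr(graphs, "failures")
    if (nrow(fails) > 0) {
      abort(paste0("unparseable SMILES: ",
                   paste(utils::head(fails$smiles, 5), collapse = ", ")))
    }
  }
  dims <- vapply(graphs, function(g) ncol(g$atom_features), integer(1))
  if (any(dims != model$scheme$atom_dim)) {
    abort("atom feature dimension does not match the model's feature scheme")
  }
  cfg <- model$config
  n <- length(graphs)
  out <- matrix(0, n, model$feature_dim)
  probs <- numeric(n)
  starts <- seq(1, n, by = 256L)
  for (s in starts) {
    ix <- s:min(s + 255L, n)
    b <- graph_batch(graphs[ix])
    fwd <- encoder_forward(cfg$kind, b, model$params, cfg$depth, cfg$readout)
    out[ix, ] <- fwd$Z
    probs[ix] <- sigmoid_(fwd$logits)
  }
  if (head) attr(out, "head_prob") <- probs
  out
}
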