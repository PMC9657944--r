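test_that("analytic gradients match finite differences for all three encoders", {
  set.seed(3)
  gs <- smiles_to_graphs(c("CC(=O)Nc1ccccc1", "CCO", "C", "CC(C)CC#N"))
  b <- epitarget:::graph_batch(gs)
  y <- c(1, 0, 1, 0)
  sc <- feature_scheme()
  for (kind in c("gcn", "ggnn", "dmpnn")) {
    cfg <- encoder_config(kind, hidden_dim = 7, depth = 3, seed = 5)
    set.seed(5)
    params <- init_encoder_params(cfg, sc)
    fwd <- epitarget:::encoder_forward(kind, b, params, cfg$depth, "sum")
    l <- epitarget:::bce_with_logits(fwd$logits, y)
    g <- epitarget:::encoder_backward(kind, b, params, fwd, l$dlogits)
    gf <- unlist(g); pf <- unlist(params)
    set.seed(99)
    idx <- sample(length(pf), 25)
    eps <- 1e-5
    num <- vapply(idx, function(i) {
      lo <- utils::relist(replace(pf, i, pf[i] - eps), params)
      hi <- utils::relist(replace(pf, i, pf[i] + eps), params)
      fh <- epitarget:::encoder_forward(kind, b, hi, cfg$depth, "sum")
      fl <- epitarget:::encoder_forward(kind, b, lo, cfg$depth, "sum")
      (epitarget:::bce_with_logits(fh$logits, y)$loss -
         epitarget:::bce_with_logits(fl$logits, y)$loss) / (2 * eps)
    }, numeric(1))
    relerr <- abs(num - gf[idx]) / pmax(1e-6, abs(num) + abs(gf[idx]))
    expect_lt(max(relerr), 1e-4)
  }
})

test_that("GCN update rule is the documented function of self and message", {
  sc <- feature_scheme()
  g <- smiles_to_graph("CC")
  d <- sc$atom_dim
  # pinned weights: identity maps, zero biases -> one step is relu(X + A X)
  params <- list(W0 = diag(d), b0 = numeric(d),
                 Ws = list(diag(d)), Wm = list(diag(d)), b = list(numeric(d)),
                 w_head = matrix(0, d, 1), b_head = 0)
  H <- propagate_gcn(g, params, depth = 1)
  X <- relu_like <- pmax(g$atom_features, 0)
  expected <- pmax(relu_like + relu_like[c(2, 1), ], 0)
  expect_equal(H, expected, tolerance = 1e-12)
})

test_that("GCN state of a single atom ignores the (empty) neighborhood", {
  sc <- feature_scheme()
  cfg <- encoder_config("gcn", hidden_dim = 9, depth = 4, seed = 2)
  set.seed(2)
  params <- init_encoder_params(cfg, sc)
  g1 <- smiles_to_graph("C")
  H1 <- propagate_gcn(g1, params, 4)
  # no neighbors means zero message at every step: the state is the repeated
  # self-update of the atom's own features
  H <- pmax(matrix(g1$atom_features %*% params$W0 + params$b0, 1), 0)
  for (t in 1:4) {
    H <- pmax(add_bias_like(H %*% params$Ws[[t]], params$b[[t]]), 0)
  }
  expect_equal(H1, H, tolerance = 1e-12)
})

test_that("GGNN gate equations reproduce closed forms at pinned parameters", {
  sc <- feature_scheme()
  d <- 6
  set.seed(8)
  params <- init_encoder_params(encoder_config("ggnn", hidden_dim = d, depth = 1, seed = 8), sc)
  g <- smiles_to_graph("C")  # isolated atom: message is exactly zero
  h0 <- drop(g$atom_features %*% params$W0) + params$b0
  # closed-form GRU at m = 0: Ml = bm
  ml <- params$bm
  z <- plogis(drop(ml %*% params$Wz) + drop(h0 %*% params$Uz) + params$bz)
  r <- plogis(drop(ml %*% params$Wr) + drop(h0 %*% params$Ur) + params$br)
  cc <- tanh(drop(ml %*% params$Wc) + drop((r * h0) %*% params$Uc) + params$bc)
  expected <- (1 - z) * h0 + z * cc
  H <- propagate_ggnn(g, params, 1)
  expect_equal(drop(H), expected, tolerance = 1e-12)

  # update gate forced fully open -> pure tanh candidate update
  params$bz <- rep(50, d)   # sigmoid saturates at 1
  H2 <- propagate_ggnn(g, params, 1)
  z2 <- rep(1, d)
  c2 <- tanh(drop(ml %*% params$Wc) + drop((r * h0) %*% params$Uc) + params$bc)
  expect_equal(drop(H2), c2, tolerance = 1e-9)
})

test_that("DMPNN matches a hand-rolled directed-edge recursion on small molecules", {
  sc <- feature_scheme()
  set.seed(21)
  params <- init_encoder_params(encoder_config("dmpnn", hidden_dim = 5, seed = 21), sc)
  for (smi in c("CC", "CCC", "CCCC", "CC(C)C", "C=CC#N")) {
    g <- smiles_to_graph(smi)
    for (depth in 1:3) {
      got <- propagate_dmpnn(g, params, depth)
      ref <- dmpnn_oracle(g, params, depth)
      expect_equal(got$edge_states, ref$edge_states, tolerance = 1e-10)
      expect_equal(got$atom_states, ref$atom_states, tolerance = 1e-10)
    }
  }
})

test_that("DMPNN exclusion rule: no immediate bounce-back on a path", {
  sc <- feature_scheme()
  set.seed(4)
  params <- init_encoder_params(encoder_config("dmpnn", hidden_dim = 4, seed = 4), sc)

  # ethane: both incoming-minus-reverse sets are empty, so every edge state
  # stays the (skip-connected) function of its initial state at any depth
  g2 <- smiles_to_graph("CC")
  h0 <- propagate_dmpnn(g2, params, 1)$edge_states
  for (depth in c(2, 5)) {
    expect_equal(propagate_dmpnn(g2, params, depth)$edge_states, h0,
                 tolerance = 1e-12)
  }

  # propane, one step: edge (1->2) receives nothing; edge (2->3) receives
  # exactly the initial state of (1->2)
  g3 <- smiles_to_graph("CCC")
  de <- g3$directed_edges
  e12 <- which(de[, "from"] == 1 & de[, "to"] == 2)
  e23 <- which(de[, "from"] == 2 & de[, "to"] == 3)
  FE <- cbind(g3$atom_features[de[, "from"], ], g3$bond_features[g3$bond_of_edge, ])
  h0e <- pmax(FE %*% params$Wi + rep(params$bi, each = nrow(FE)), 0)
  s1 <- propagate_dmpnn(g3, params, 1)$edge_states
  expect_equal(s1[e12, ], h0e[e12, ], tolerance = 1e-12)   # empty message
  expect_equal(s1[e23, ], pmax(h0e[e23, ] + drop(h0e[e12, ] %*% params$Wm), 0),
               tolerance = 1e-12)
})

test_that("molecule embeddings are invariant to atom relabelling", {
  d <- small_target_data()
  gs <- small_graphs()
  set.seed(10)
  for (kind in c("gcn", "ggnn", "dmpnn")) {
    m <- train_encoder(d[1:60, ], tiny_encoder(kind), graphs = gs[1:60])
    sub <- gs[61:70]
    z <- embed(m, sub)
    perms <- lapply(sub, function(g) sample(g$n_atoms))
    zp <- embed(m, purrr::map2(sub, perms, permute_molgraph))
    expect_equal(z, zp, tolerance = 1e-6)
  }
})

test_that("T message-passing steps see exactly the T-bond neighborhood", {
  sc <- feature_scheme()
  set.seed(12)
  cfg <- encoder_config("gcn", hidden_dim = 8, depth = 3, seed = 12)
  params <- init_encoder_params(cfg, sc)
  # a 12-carbon chain vs the same chain with a distal O substitution at the end
  g_a <- smiles_to_graph("CCCCCCCCCCCC")
  g_b <- smiles_to_graph("CCCCCCCCCCCO")
  Ha <- propagate_gcn(g_a, params, 3)
  Hb <- propagate_gcn(g_b, params, 3)
  # atoms more than 3 bonds from the edit (indices 1..8) are untouched
  expect_equal(Ha[1:8, ], Hb[1:8, ], tolerance = 1e-12)
  # the edit is visible within the receptive field
  expect_gt(max(abs(Ha[10:12, ] - Hb[10:12, ])), 1e-6)
})

test_that("training is reproducible from the seed and actually learns", {
  d <- small_target_data()
  gs <- small_graphs()
  cfg <- encoder_config("dmpnn", hidden_dim = 32, depth = 3, epochs = 30,
                        batch_size = 25, seed = 77)
  m1 <- train_encoder(d, cfg, graphs = gs)
  m2 <- train_encoder(d, cfg, graphs = gs)
  expect_identical(rlang::hash(m1$params), rlang::hash(m2$params))
  expect_lt(tail(m1$loss_history, 1), m1$loss_history[1])

  # the motif task is linearly separable within the receptive field:
  # the trained head should fit the training set almost perfectly
  z <- embed(m1, gs, head = TRUE)
  acc <- mean((attr(z, "head_prob") > 0.5) == (d$label == "active"))
  expect_gte(acc, 0.95)
})

test_that("encoder training validates its inputs", {
  d <- small_target_data()[1:10, ]
  d$label <- "active"
  expect_error(train_encoder(d, tiny_encoder()), "both classes")
  d2 <- small_target_data()[1:10, ]
  d2$label[1] <- "unknown"
  expect_error(train_encoder(d2, tiny_encoder()), "binary")
})

test_that("embedding is deterministic, order-stable, and batching-independent", {
  d <- small_target_data()
  gs <- small_graphs()
  m <- train_encoder(d[1:50, ], tiny_encoder("gcn"), graphs = gs[1:50])
  z_all <- embed(m, gs[1:20])
  z_one <- embed(m, gs[5])
  expect_equal(z_all[5, , drop = FALSE], z_one, tolerance = 1e-12)
  # duplicated molecule -> identical rows
  z_dup <- embed(m, list(gs[[3]], gs[[3]]))
  expect_equal(z_dup[1, ], z_dup[2, ])
  # two spellings of one molecule -> identical embeddings
  z_sp <- embed(m, smiles_to_graphs(c("CCO", "OCC")))
  expect_equal(z_sp[1, ], z_sp[2, ], tolerance = 1e-8)
  # feature-scheme mismatch is a dimension error
  other <- feature_scheme(elements = c("C", "N", "O"))
  expect_error(embed(m, smiles_to_graphs("CC", scheme = other)), "dimension")
})

test_that("readout pooling is order-invariant with the documented semantics", {
  s <- matrix(c(1, 2, 3, 4, 5, 6), 3, 2)
  expect_equal(readout(s, "sum"), c(6, 15))
  expect_equal(readout(s, "mean"), c(2, 5))
  expect_equal(readout(s[c(3, 1, 2), ], "sum"), readout(s, "sum"))
  k <- 4
  rep_state <- matrix(rep(c(1.5, -2), each = k), k, 2)
  expect_equal(readout(rep_state, "mean"), c(1.5, -2))
  expect_equal(readout(rep_state, "sum"), k * c(1.5, -2))
})
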