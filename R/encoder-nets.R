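# The three message-passing architectures. Each has an init_*, forward_*,
# and backward_* triple operating on a batched graph (see graph-batch.R).
# Node states follow h_i^t = U(h_i^{t-1}, m_i^t): the update U is
#   GCN   relu(W_self h + W_msg m + b), per-step weights
#   GGNN  a gated recurrent unit driven by the aggregated message
#   DMPNN states on directed bonds; the message into edge v->w aggregates
#         incoming edges k->v excluding the reverse w->v, with a skip
#         connection to the initial edge state
# All backward passes are analytic reverse-mode gradients, checked against
# finite differences in the test suite.

add_bias <- function(M, b) add_bias_cpp(M, b)

## ----- GCN ------------------------------------------------------------------

init_gcn_params <- function(atom_dim, hidden_dim, depth) {
  list(
    W0 = glorot(atom_dim, hidden_dim), b0 = zeros(hidden_dim),
    Ws = lapply(seq_len(depth), function(i) glorot(hidden_dim, hidden_dim)),
    Wm = lapply(seq_len(depth), function(i) glorot(hidden_dim, hidden_dim)),
    b = lapply(seq_len(depth), function(i) zeros(hidden_dim)),
    w_head = glorot(hidden_dim, 1), b_head = 0
  )
}

forward_gcn <- function(batch, params, depth, readout_mode, dropout = 0,
                        training = FALSE) {
  H0pre <- add_bias(batch$X %*% params$W0, params$b0)
  H <- relu(H0pre)
  Hs <- vector("list", depth + 1); Hs[[1]] <- H
  Ms <- vector("list", depth); masks <- vector("list", depth)
  for (t in seq_len(depth)) {
    Mt <- msg_atoms(batch, H)
    Hpre <- add_bias(H %*% params$Ws[[t]] + Mt %*% params$Wm[[t]], params$b[[t]])
    H <- relu(Hpre)
    if (training && dropout > 0) {
      mk <- matrix(runif(length(H)) >= dropout, nrow(H)) / (1 - dropout)
      H <- H * mk; masks[[t]] <- mk
    }
    Ms[[t]] <- Mt; Hs[[t + 1]] <- H
  }
  Z <- readout_fwd(batch, H, readout_mode)
  logits <- drop(Z %*% params$w_head) + params$b_head
  list(Z = Z, logits = logits, H = H,
       cache = list(H0pre = H0pre, Hs = Hs, Ms = Ms, masks = masks,
                    mode = readout_mode))
}

backward_gcn <- function(batch, params, fwd, dlogits, dZ_extra = NULL) {
  ca <- fwd$cache
  depth <- length(ca$Ms)
  dZ <- outer(dlogits, drop(params$w_head))
  if (!is.null(dZ_extra)) dZ <- dZ + dZ_extra
  g <- list(W0 = NULL, b0 = NULL, Ws = vector("list", depth),
            Wm = vector("list", depth), b = vector("list", depth),
            w_head = crossprod(fwd$Z, dlogits), b_head = sum(dlogits))
  dH <- readout_bwd(batch, dZ, ca$mode)
  for (t in rev(seq_len(depth))) {
    if (!is.null(ca$masks[[t]])) dH <- dH * ca$masks[[t]]
    dHpre <- relu_bwd_cpp(dH, ca$Hs[[t + 1]])
    g$Ws[[t]] <- crossprod(ca$Hs[[t]], dHpre)
    g$Wm[[t]] <- crossprod(ca$Ms[[t]], dHpre)
    g$b[[t]] <- colSums(dHpre)
    dH <- dHpre %*% t(params$Ws[[t]]) +
      msg_atoms_t(batch, dHpre %*% t(params$Wm[[t]]))
  }
  dH0pre <- relu_bwd_cpp(dH, ca$H0pre)
  g$W0 <- crossprod(batch$X, dH0pre)
  g$b0 <- colSums(dH0pre)
  g
}

## ----- GGNN -----------------------------------------------------------------

init_ggnn_params <- function(atom_dim, hidden_dim, depth) {
  d <- hidden_dim
  list(
    W0 = glorot(atom_dim, d), b0 = zeros(d),
    Wmsg = glorot(d, d), bm = zeros(d),
    Wz = glorot(d, d), Uz = glorot(d, d), bz = zeros(d),
    Wr = glorot(d, d), Ur = glorot(d, d), br = zeros(d),
    Wc = glorot(d, d), Uc = glorot(d, d), bc = zeros(d),
    w_head = glorot(d, 1), b_head = 0
  )
}

forward_ggnn <- function(batch, params, depth, readout_mode, dropout = 0,
                         training = FALSE) {
  H <- add_bias(batch$X %*% params$W0, params$b0)
  steps <- vector("list", depth); masks <- vector("list", depth)
  for (t in seq_len(depth)) {
    Mraw <- msg_atoms(batch, H)
    Ml <- add_bias(Mraw %*% params$Wmsg, params$bm)
    Zg <- sigmoid_(add_bias(Ml %*% params$Wz + H %*% params$Uz, params$bz))
    Rg <- sigmoid_(add_bias(Ml %*% params$Wr + H %*% params$Ur, params$br))
    RH <- Rg * H
    Cg <- tanh(add_bias(Ml %*% params$Wc + RH %*% params$Uc, params$bc))
    Hnew <- (1 - Zg) * H + Zg * Cg
    if (training && dropout > 0) {
      mk <- matrix(runif(length(Hnew)) >= dropout, nrow(Hnew)) / (1 - dropout)
      Hnew <- Hnew * mk; masks[[t]] <- mk
    }
    steps[[t]] <- list(Hprev = H, Mraw = Mraw, Ml = Ml, Zg = Zg, Rg = Rg,
                       RH = RH, Cg = Cg)
    H <- Hnew
  }
  Z <- readout_fwd(batch, H, readout_mode)
  logits <- drop(Z %*% params$w_head) + params$b_head
  list(Z = Z, logits = logits, H = H,
       cache = list(steps = steps, masks = masks, mode = readout_mode))
}

backward_ggnn <- function(batch, params, fwd, dlogits, dZ_extra = NULL) {
  ca <- fwd$cache
  depth <- length(ca$steps)
  dZ <- outer(dlogits, drop(params$w_head))
  if (!is.null(dZ_extra)) dZ <- dZ + dZ_extra
  g <- lapply(params, zero_like)
  g$w_head <- crossprod(fwd$Z, dlogits)
  g$b_head <- sum(dlogits)
  dH <- readout_bwd(batch, dZ, ca$mode)
  for (t in rev(seq_len(depth))) {
    if (!is.null(ca$masks[[t]])) dH <- dH * ca$masks[[t]]
    st <- ca$steps[[t]]
    dZg <- dH * (st$Cg - st$Hprev)
    dCg <- dH * st$Zg
    dHprev <- dH * (1 - st$Zg)
    dCpre <- dCg * (1 - st$Cg^2)
    g$Wc <- g$Wc + crossprod(st$Ml, dCpre)
    g$Uc <- g$Uc + crossprod(st$RH, dCpre)
    g$bc <- g$bc + colSums(dCpre)
    dMl <- dCpre %*% t(params$Wc)
    dRH <- dCpre %*% t(params$Uc)
    dRg <- dRH * st$Hprev
    dHprev <- dHprev + dRH * st$Rg
    dZpre <- dZg * st$Zg * (1 - st$Zg)
    g$Wz <- g$Wz + crossprod(st$Ml, dZpre)
    g$Uz <- g$Uz + crossprod(st$Hprev, dZpre)
    g$bz <- g$bz + colSums(dZpre)
    dMl <- dMl + dZpre %*% t(params$Wz)
    dHprev <- dHprev + dZpre %*% t(params$Uz)
    dRpre <- dRg * st$Rg * (1 - st$Rg)
    g$Wr <- g$Wr + crossprod(st$Ml, dRpre)
    g$Ur <- g$Ur + crossprod(st$Hprev, dRpre)
    g$br <- g$br + colSums(dRpre)
    dMl <- dMl + dRpre %*% t(params$Wr)
    dHprev <- dHprev + dRpre %*% t(params$Ur)
    g$Wmsg <- g$Wmsg + crossprod(st$Mraw, dMl)
    g$bm <- g$bm + colSums(dMl)
    dMraw <- dMl %*% t(params$Wmsg)
    dH <- dHprev + msg_atoms_t(batch, dMraw)
  }
  g$W0 <- crossprod(batch$X, dH)
  g$b0 <- colSums(dH)
  g
}

## ----- DMPNN ----------------------------------------------------------------

init_dmpnn_params <- function(atom_dim, bond_dim, hidden_dim) {
  d <- hidden_dim
  list(
    Wi = glorot(atom_dim + bond_dim, d), bi = zeros(d),
    Wm = glorot(d, d),
    Wa = glorot(atom_dim + d, d), ba = zeros(d),
    w_head = glorot(d, 1), b_head = 0
  )
}

forward_dmpnn <- function(batch, params, depth, readout_mode, dropout = 0,
                          training = FALSE) {
  d <- ncol(params$Wm)
  E <- batch$n_edges_total
  H0pre <- if (E > 0) add_bias(batch$FE %*% params$Wi, params$bi) else matrix(0, 0, d)
  H0e <- relu(H0pre)
  He <- H0e
  Hes <- vector("list", depth); Msv <- vector("list", depth)
  masks <- vector("list", depth)
  for (t in seq_len(depth)) {
    Mt <- msg_edges(batch, He)
    He <- relu(H0e + Mt %*% params$Wm)
    if (training && dropout > 0 && E > 0) {
      mk <- matrix(runif(length(He)) >= dropout, nrow(He)) / (1 - dropout)
      He <- He * mk; masks[[t]] <- mk
    }
    Msv[[t]] <- Mt; Hes[[t]] <- He
  }
  Mv <- edges_to_atoms(batch, He)
  CatV <- cbind(batch$X, Mv)
  Hv_pre <- add_bias(CatV %*% params$Wa, params$ba)
  Hv <- relu(Hv_pre)
  Z <- readout_fwd(batch, Hv, readout_mode)
  logits <- drop(Z %*% params$w_head) + params$b_head
  list(Z = Z, logits = logits, H = Hv, He = He,
       cache = list(H0pre = H0pre, H0e = H0e, Hes = Hes, Msv = Msv,
                    masks = masks, Mv = Mv, CatV = CatV, Hv = Hv,
                    mode = readout_mode))
}

backward_dmpnn <- function(batch, params, fwd, dlogits, dZ_extra = NULL) {
  ca <- fwd$cache
  depth <- length(ca$Hes)
  da <- ncol(batch$X)
  d <- ncol(params$Wm)
  dZ <- outer(dlogits, drop(params$w_head))
  if (!is.null(dZ_extra)) dZ <- dZ + dZ_extra
  g <- lapply(params, zero_like)
  g$w_head <- crossprod(fwd$Z, dlogits)
  g$b_head <- sum(dlogits)
  dHv <- readout_bwd(batch, dZ, ca$mode)
  dHv_pre <- relu_bwd_cpp(dHv, ca$Hv)
  g$Wa <- crossprod(ca$CatV, dHv_pre)
  g$ba <- colSums(dHv_pre)
  dCat <- dHv_pre %*% t(params$Wa)
  dMv <- dCat[, (da + 1):(da + d), drop = FALSE]
  dHe <- edges_to_atoms_t(batch, dMv)
  dH0e <- matrix(0, nrow(dHe), d)
  for (t in rev(seq_len(depth))) {
    if (!is.null(ca$masks[[t]])) dHe <- dHe * ca$masks[[t]]
    dpre <- relu_bwd_cpp(dHe, ca$Hes[[t]])
    g$Wm <- g$Wm + crossprod(ca$Msv[[t]], dpre)
    dH0e <- dH0e + dpre
    dHe <- msg_edges_t(batch, dpre %*% t(params$Wm))
  }
  dH0e <- dH0e + dHe   # gradient flowing into He^0 = H0e from the first message
  dH0pre <- relu_bwd_cpp(dH0e, ca$H0pre)
  if (nrow(dH0pre) > 0) {
    g$Wi <- crossprod(batch$FE, dH0pre)
    g$bi <- colSums(dH0pre)
  }
  g
}
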