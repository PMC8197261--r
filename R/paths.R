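# The three feature-extraction path layers. Each layer maps the current
# [N x M] atom-feature matrix to an updated one using pair features over
# the neighbour set N(i) (which includes i itself: the SELF channel).
#
# Implementation note: pair features are computed only for the K ordered
# pairs (i, j), j in N(i), enumerated once per graph (graph$cache). The
# neighbourhood sum is a rowsum over the pair group index. Backward passes
# mirror the forwards exactly; gradient correctness is enforced by the
# finite-difference test suite.

#' Parameters of one node-path layer
#'
#' @param W_np `[M x 2M]` pair weight; `B_np` length-M pair bias;
#'   `W_n` `[M x M]` update weight; `B_n` length-M update bias.
#' @param B_np,W_n,B_n See `W_np`.
#' @return List of class `node_path_params`.
#' @export
node_path_params <- function(W_np, B_np, W_n, B_n) {
  M <- nrow(W_np)
  check_matrix(W_np, M, 2 * M, "W_np")
  check_matrix(W_n, M, M, "W_n")
  stopifnot(length(B_np) == M, length(B_n) == M)
  structure(list(W_np = W_np, B_np = as.numeric(B_np),
                 W_n = W_n, B_n = as.numeric(B_n)),
            class = "node_path_params")
}

#' Parameters of one edge-path layer
#'
#' In addition to the dense weights, the edge path carries one scalar edge
#' weight per bond channel (`w`, length 5 over SELF/SINGLE/DOUBLE/TRIPLE/
#' AROMATIC) and a bias `c`, realising a 1x1 convolution across the five
#' adjacency channels. With `fixed_mode = TRUE` the categorical values
#' w = (1, 2, 3, 4, 5), c = 0 are used and excluded from training.
#'
#' @param W_ep,B_ep,W_e,B_e Dense weights/biases shaped as in
#'   [node_path_params()].
#' @param w Length-5 numeric edge weights, one per bond channel.
#' @param c Scalar edge bias.
#' @param fixed_mode Use the fixed categorical edge values?
#' @return List of class `edge_path_params`.
#' @export
edge_path_params <- function(W_ep, B_ep, W_e, B_e, w = 0.1 * (1:5), c = 0,
                             fixed_mode = FALSE) {
  M <- nrow(W_ep)
  check_matrix(W_ep, M, 2 * M, "W_ep")
  check_matrix(W_e, M, M, "W_e")
  stopifnot(length(B_ep) == M, length(B_e) == M, length(w) == 5,
            length(c) == 1)
  if (fixed_mode) { w <- as.numeric(1:5); c <- 0 }
  structure(list(W_ep = W_ep, B_ep = as.numeric(B_ep), W_e = W_e,
                 B_e = as.numeric(B_e), w = as.numeric(w), c = as.numeric(c),
                 fixed_mode = isTRUE(fixed_mode)),
            class = "edge_path_params")
}

#' Parameters of one 3D-path layer
#'
#' @param W_tp `[M x 2M]` pair weight over relative coordinates; `B_tp`
#'   its bias; `W_tq` `[M x M]` and `B_tq` the intermediate update;
#'   `W_t` `[M x 2M]` the self-concatenation weight (used when
#'   `include_self`); `W_ns` `[M x M]` the no-self weight (used otherwise).
#' @param B_tp,W_tq,B_tq,W_t,W_ns See `W_tp`.
#' @param include_self Keep the atom's own feature via concatenation?
#' @return List of class `threed_path_params`.
#' @export
threed_path_params <- function(W_tp, B_tp, W_tq, B_tq, W_t = NULL,
                               include_self = TRUE, W_ns = NULL) {
  M <- nrow(W_tp)
  check_matrix(W_tp, M, 2 * M, "W_tp")
  check_matrix(W_tq, M, M, "W_tq")
  stopifnot(length(B_tp) == M, length(B_tq) == M)
  if (include_self) check_matrix(W_t, M, 2 * M, "W_t")
  else check_matrix(W_ns, M, M, "W_ns")
  structure(list(W_tp = W_tp, B_tp = as.numeric(B_tp), W_tq = W_tq,
                 B_tq = as.numeric(B_tq), W_t = W_t, W_ns = W_ns,
                 include_self = isTRUE(include_self)),
            class = "threed_path_params")
}

check_H <- function(H, graph, M) {
  if (!is.matrix(H)) H <- matrix(H, ncol = M)
  if (nrow(H) != graph$n_atoms || ncol(H) != M)
    stop_shape("feature matrix H", c(graph$n_atoms, M), dim(H))
  if (!all(is.finite(H))) stop("H must be finite", call. = FALSE)
  H
}

# ---- node path ----

node_fwd <- function(H, gc, par) {
  Pair <- cbind(H[gc$pi, , drop = FALSE], H[gc$pj, , drop = FALSE])
  Z1 <- add_bias(Pair %*% t(par$W_np), par$B_np)
  P <- relu(Z1)
  S <- rowsum0(P, gc$pi)
  Z2 <- add_bias(S %*% t(par$W_n), par$B_n)
  list(H = relu(Z2),
       cache = list(Pair = Pair, m1 = Z1 > 0, S = S, m2 = Z2 > 0, gc = gc))
}

node_bwd <- function(dH, cache, par) {
  gc <- cache$gc
  M <- ncol(dH)
  dZ2 <- dH * cache$m2
  gW_n <- t(dZ2) %*% cache$S
  gB_n <- colSums(dZ2)
  dS <- dZ2 %*% par$W_n
  dP <- dS[gc$pi, , drop = FALSE]
  dZ1 <- dP * cache$m1
  gW_np <- t(dZ1) %*% cache$Pair
  gB_np <- colSums(dZ1)
  dPair <- dZ1 %*% par$W_np
  dHin <- rowsum0(dPair[, seq_len(M), drop = FALSE], gc$pi) +
          rowsum0(dPair[, M + seq_len(M), drop = FALSE], gc$pj)
  list(dH = dHin,
       grads = list(W_np = gW_np, B_np = gB_np, W_n = gW_n, B_n = gB_n))
}

#' One node-path update
#'
#' Pair features are built from the concatenated features of each atom and
#' its neighbours (self included), passed through a rectified linear layer,
#' summed over the neighbourhood and transformed again:
#' `H_i' = relu(sum_{j in N(i)} W_n relu(W_np (H_i || H_j) + B_np) + B_n)`.
#'
#' @param H `[N x M]` feature matrix.
#' @param graph A [molecular_graph()].
#' @param params [node_path_params()].
#' @return Updated `[N x M]` matrix, elementwise nonnegative.
#' @export
node_path_update <- function(H, graph, params) {
  H <- check_H(H, graph, nrow(params$W_np))
  node_fwd(H, graph$cache, params)$H
}

# ---- edge path ----

#' Edge-parameter matrix from the adjacency stack
#'
#' `E[i, j] = sum_b w[b] A[b, i, j] + c`: a 1x1 convolution across the five
#' bond channels yielding one scalar per atom pair. In fixed mode the
#' categorical values w = (1..5), c = 0 reproduce the classic labelling
#' (1 self, 2 single, 3 double, 4 triple, 5 aromatic).
#'
#' @param A `[5 x N x N]` adjacency stack.
#' @param w Length-5 channel weights.
#' @param c Scalar bias.
#' @return `N x N` numeric matrix.
#' @export
edge_parameter_matrix <- function(A, w, c = 0) {
  stopifnot(length(dim(A)) == 3, dim(A)[1] == 5, length(w) == 5)
  n <- dim(A)[2]
  E <- matrix(c, n, n)
  for (b in 1:5) E <- E + w[b] * A[b, , ]
  E
}

edge_fwd <- function(H, gc, par) {
  Evec <- par$w[gc$chan] + par$c
  Pair <- cbind(H[gc$pi, , drop = FALSE], H[gc$pj, , drop = FALSE])
  G <- Pair %*% t(par$W_ep)
  Z1 <- add_bias(Evec * G, par$B_ep)
  P <- relu(Z1)
  S <- rowsum0(P, gc$pi)
  Z2 <- add_bias(S %*% t(par$W_e), par$B_e)
  list(H = relu(Z2),
       cache = list(Pair = Pair, G = G, Evec = Evec, m1 = Z1 > 0, S = S,
                    m2 = Z2 > 0, gc = gc))
}

edge_bwd <- function(dH, cache, par) {
  gc <- cache$gc
  M <- ncol(dH)
  dZ2 <- dH * cache$m2
  gW_e <- t(dZ2) %*% cache$S
  gB_e <- colSums(dZ2)
  dS <- dZ2 %*% par$W_e
  dZ1 <- dS[gc$pi, , drop = FALSE] * cache$m1
  gB_ep <- colSums(dZ1)
  dEvec <- rowSums(dZ1 * cache$G)
  dG <- cache$Evec * dZ1
  gW_ep <- t(dG) %*% cache$Pair
  dPair <- dG %*% par$W_ep
  dHin <- rowsum0(dPair[, seq_len(M), drop = FALSE], gc$pi) +
          rowsum0(dPair[, M + seq_len(M), drop = FALSE], gc$pj)
  gw <- numeric(5)
  for (b in 1:5) gw[b] <- sum(dEvec[gc$chan == b])
  grads <- list(W_ep = gW_ep, B_ep = gB_ep, W_e = gW_e, B_e = gB_e)
  if (!par$fixed_mode) { grads$w <- gw; grads$c <- sum(dEvec) }
  list(dH = dHin, grads = grads)
}

#' One edge-path update
#'
#' As the node path, but each pair's pre-activation is scaled by the scalar
#' edge parameter: `P_ij = relu(E_ij W_ep (H_i || H_j) + B_ep)`, then
#' `H_i' = relu(sum_{j in N(i)} W_e P_ij + B_e)`. With `E == 1` everywhere
#' and shared weights this reduces exactly to the node path.
#'
#' @inheritParams node_path_update
#' @param params [edge_path_params()].
#' @return Updated `[N x M]` matrix.
#' @export
edge_path_update <- function(H, graph, params) {
  H <- check_H(H, graph, nrow(params$W_ep))
  edge_fwd(H, graph$cache, params)$H
}

# ---- 3D path ----

#' Relative coordinates
#'
#' `R[k, i, j] = C[i, k] - C[j, k]` for k in (x, y, z): antisymmetric in
#' (i, j), zero diagonal, invariant under translation of `C` but not under
#' rotation.
#'
#' @param C `[N x 3]` coordinate matrix.
#' @return `[3 x N x N]` array.
#' @export
relative_coords <- function(C) {
  if (is.null(C))
    stop("coordinates are missing; embed the molecule in 3D or supply an ",
         "SDF with coordinates", call. = FALSE)
  C <- as.matrix(C)
  stopifnot(ncol(C) == 3, all(is.finite(C)))
  n <- nrow(C)
  R <- array(0, c(3L, n, n), dimnames = list(c("x", "y", "z"), NULL, NULL))
  for (k in 1:3) R[k, , ] <- outer(C[, k], C[, k], `-`)
  R
}

threed_fwd <- function(H, gc, par) {
  if (is.null(gc$s))
    stop("coordinates are missing; embed the molecule in 3D or supply an ",
         "SDF with coordinates", call. = FALSE)
  Pair <- cbind(H[gc$pi, , drop = FALSE], H[gc$pj, , drop = FALSE])
  G <- Pair %*% t(par$W_tp)
  Z1 <- add_bias(gc$s * G, par$B_tp)
  P <- relu(Z1)
  S <- rowsum0(P, gc$pi)
  ZQ <- add_bias(S %*% t(par$W_tq), par$B_tq)
  Q <- relu(ZQ)
  if (par$include_self) {
    HQ <- cbind(H, Q)
    Z2 <- HQ %*% t(par$W_t)
  } else {
    HQ <- Q
    Z2 <- Q %*% t(par$W_ns)
  }
  list(H = relu(Z2),
       cache = list(Pair = Pair, G = G, m1 = Z1 > 0, S = S, mQ = ZQ > 0,
                    HQ = HQ, m2 = Z2 > 0, gc = gc))
}

threed_bwd <- function(dH, cache, par) {
  gc <- cache$gc
  M <- ncol(dH)
  dZ2 <- dH * cache$m2
  if (par$include_self) {
    gW_t <- t(dZ2) %*% cache$HQ
    dHQ <- dZ2 %*% par$W_t
    dHself <- dHQ[, seq_len(M), drop = FALSE]
    dQ <- dHQ[, M + seq_len(M), drop = FALSE]
  } else {
    gW_t <- t(dZ2) %*% cache$HQ  # cache$HQ is Q here
    dQ <- dZ2 %*% par$W_ns
    dHself <- matrix(0, nrow(dH), M)
  }
  dZQ <- dQ * cache$mQ
  gW_tq <- t(dZQ) %*% cache$S
  gB_tq <- colSums(dZQ)
  dS <- dZQ %*% par$W_tq
  dZ1 <- dS[gc$pi, , drop = FALSE] * cache$m1
  gB_tp <- colSums(dZ1)
  dG <- gc$s * dZ1
  gW_tp <- t(dG) %*% cache$Pair
  dPair <- dG %*% par$W_tp
  dHin <- dHself +
          rowsum0(dPair[, seq_len(M), drop = FALSE], gc$pi) +
          rowsum0(dPair[, M + seq_len(M), drop = FALSE], gc$pj)
  grads <- list(W_tp = gW_tp, B_tp = gB_tp, W_tq = gW_tq, B_tq = gB_tq)
  if (par$include_self) grads$W_t <- gW_t else grads$W_ns <- gW_t
  list(dH = dHin, grads = grads)
}

#' One 3D-path update
#'
#' Pair features are weighted by the summed relative coordinates:
#' `P_ij = relu(sum_k R(k)_ij W_tp (H_i || H_j) + B_tp)`, accumulated into
#' `Q_i = relu(sum_{j in N(i)} W_tq P_ij + B_tq)`. Because `R_ii = 0`, `Q_i`
#' carries no trace of the atom's own feature, so by default the update
#' reattaches it: `H_i' = relu(W_t (H_i || Q_i))`. With
#' `include_self = FALSE` the variant `H_i' = relu(W_ns Q_i)` is used.
#' Outputs are invariant under translation of the coordinates but change
#' under generic rotation.
#'
#' @inheritParams node_path_update
#' @param params [threed_path_params()].
#' @return Updated `[N x M]` matrix.
#' @export
threed_path_update <- function(H, graph, params) {
  H <- check_H(H, graph, nrow(params$W_tp))
  threed_fwd(H, graph$cache, params)$H
}

path_fwd <- function(path) {
  switch(path, node = node_fwd, edge = edge_fwd, `3d` = threed_fwd)
}
path_bwd <- function(path) {
  switch(path, node = node_bwd, edge = edge_bwd, `3d` = threed_bwd)
}
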