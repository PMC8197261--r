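# Naive per-node, per-neighbour reference implementations of every update
# equation, written as explicit loops over scalar/vector operations. They
# are intentionally independent of the vectorized production code and are
# the oracle it is compared against.

relu0 <- function(x) pmax(x, 0)

# neighbour set of node i: i itself plus all atoms bonded to it
nbrs_of <- function(graph, i) {
  b <- graph$bonds
  sort(unique(c(i, b$j[b$i == i], b$i[b$j == i])))
}

oracle_node_update <- function(H, graph, par) {
  N <- nrow(H); M <- ncol(H)
  out <- matrix(0, N, M)
  for (i in seq_len(N)) {
    s <- par$B_n
    for (j in nbrs_of(graph, i)) {
      Pij <- relu0(par$W_np %*% c(H[i, ], H[j, ]) + par$B_np)
      s <- s + par$W_n %*% Pij
    }
    out[i, ] <- relu0(s)
  }
  out
}

oracle_E <- function(A, w, cc) {
  n <- dim(A)[2]
  E <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    v <- cc
    for (b in 1:5) v <- v + w[b] * A[b, i, j]
    E[i, j] <- v
  }
  E
}

oracle_edge_update <- function(H, graph, par) {
  N <- nrow(H); M <- ncol(H)
  E <- oracle_E(graph$A, par$w, par$c)
  out <- matrix(0, N, M)
  for (i in seq_len(N)) {
    s <- par$B_e
    for (j in nbrs_of(graph, i)) {
      Pij <- relu0(E[i, j] * (par$W_ep %*% c(H[i, ], H[j, ])) + par$B_ep)
      s <- s + par$W_e %*% Pij
    }
    out[i, ] <- relu0(s)
  }
  out
}

oracle_threed_update <- function(H, graph, par) {
  N <- nrow(H); M <- ncol(H)
  R <- relative_coords(graph$C)
  out <- matrix(0, N, M)
  for (i in seq_len(N)) {
    sq <- par$B_tq
    for (j in nbrs_of(graph, i)) {
      z <- par$B_tp
      for (k in 1:3)
        z <- z + R[k, i, j] * (par$W_tp %*% c(H[i, ], H[j, ]))
      sq <- sq + par$W_tq %*% relu0(z)
    }
    Qi <- relu0(sq)
    out[i, ] <- if (par$include_self) relu0(par$W_t %*% c(H[i, ], Qi))
                else relu0(par$W_ns %*% Qi)
  }
  out
}

oracle_attention <- function(H_init, H_paths, par) {
  N <- nrow(H_init); M <- ncol(H_init)
  paths <- names(par$W_k)
  P <- length(paths)
  e <- matrix(0, N, P, dimnames = list(NULL, paths))
  for (i in seq_len(N)) {
    u <- relu0(as.numeric(H_init[i, ] %*% par$W_init))
    for (k in seq_len(P)) {
      v <- relu0(as.numeric(H_paths[[paths[k]]][i, ] %*% par$W_k[[paths[k]]]))
      e[i, k] <- as.numeric(par$W_att %*% c(u, v))
    }
  }
  alpha <- matrix(0, N, P, dimnames = list(NULL, paths))
  for (i in seq_len(N))
    alpha[i, ] <- exp(e[i, ]) / sum(exp(e[i, ]))
  H <- matrix(0, N, M)
  for (i in seq_len(N)) {
    s <- numeric(M)
    for (k in seq_len(P)) s <- s + alpha[i, k] * H_paths[[paths[k]]][i, ]
    H[i, ] <- relu0(as.numeric(par$W_agg %*% s))
  }
  list(e = e, alpha = alpha, H = H)
}

# ---- random fixtures ----

rand_graph <- function(seed, with_coords = TRUE, n_max = 8L) {
  spec <- synth_spec(n_molecules = 1, atoms_range = c(2L, n_max),
                     seed = seed)
  g <- make_dataset(spec)[[1]]$graph
  if (!with_coords) g$C <- NULL
  g
}

# random dense path/aggregation parameters at width M (small values keep
# activations in a generic regime)
rand_node_par <- function(M, seed) {
  set.seed(seed)
  node_path_params(matrix(rnorm(M * 2 * M, 0, 0.4), M), rnorm(M, 0, 0.2),
                   matrix(rnorm(M * M, 0, 0.4), M), rnorm(M, 0, 0.2))
}
rand_edge_par <- function(M, seed, fixed = FALSE) {
  set.seed(seed)
  edge_path_params(matrix(rnorm(M * 2 * M, 0, 0.4), M), rnorm(M, 0, 0.2),
                   matrix(rnorm(M * M, 0, 0.4), M), rnorm(M, 0, 0.2),
                   w = rnorm(5, 0, 0.5), c = rnorm(1, 0, 0.2),
                   fixed_mode = fixed)
}
rand_threed_par <- function(M, seed, include_self = TRUE) {
  set.seed(seed)
  threed_path_params(matrix(rnorm(M * 2 * M, 0, 0.4), M), rnorm(M, 0, 0.2),
                     matrix(rnorm(M * M, 0, 0.4), M), rnorm(M, 0, 0.2),
                     W_t = if (include_self) matrix(rnorm(M * 2 * M, 0, 0.4), M),
                     include_self = include_self,
                     W_ns = if (!include_self) matrix(rnorm(M * M, 0, 0.4), M))
}
rand_att_par <- function(M, paths, seed) {
  set.seed(seed)
  W_k <- lapply(paths, function(p) matrix(rnorm(M * M, 0, 0.4), M))
  names(W_k) <- paths
  attention_params(matrix(rnorm(M * M, 0, 0.4), M), W_k,
                   matrix(rnorm(2 * M, 0, 0.4), 1),
                   matrix(rnorm(M * M, 0, 0.4), M))
}
rand_H <- function(N, M, seed) {
  set.seed(seed)
  matrix(abs(rnorm(N * M, 0.4, 0.3)), N, M)
}

# apply a permutation of atom indices to a molecular graph
permute_graph <- function(g, perm) {
  inv <- order(perm)
  bonds <- g$bonds
  if (nrow(bonds)) {
    bonds$i <- inv[bonds$i]
    bonds$j <- inv[bonds$j]
  }
  molecular_graph(g$elements[perm], bonds,
                  if (!is.null(g$C)) g$C[perm, , drop = FALSE],
                  num_h = g$num_h[perm], charge = g$charge[perm],
                  id = paste0(g$id, "_perm"))
}

# small helper: shrink a graph's feature matrix to width M for fast tests
shrink_features <- function(g, M, seed) {
  set.seed(seed)
  g$H_init <- matrix(abs(rnorm(g$n_atoms * M, 0.5, 0.3)), g$n_atoms, M)
  g
}
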