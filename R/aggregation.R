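# Aggregation of per-path atom features into one feature per atom, either
# by per-atom attention over the enabled paths or by concatenation /
# summing / elementwise maximum.

#' Attention-aggregation parameters
#'
#' @param W_init `[M x M]` transform of the initial atom feature.
#' @param W_k Named list of `[M x M]` matrices, one per enabled path
#'   (names among `"node"`, `"edge"`, `"3d"`).
#' @param W_att `[1 x 2M]` scoring weight: the attention score of path p at
#'   atom i is `e_i^p = W_att (relu(H_i^init W_init) || relu(H_i^p W_p))`,
#'   a scalar so the softmax over paths is well defined.
#' @param W_agg `[M x M]` output transform.
#' @return List of class `attention_params`.
#' @export
attention_params <- function(W_init, W_k, W_att, W_agg) {
  M <- nrow(W_init)
  check_matrix(W_init, M, M, "W_init")
  check_matrix(W_att, 1, 2 * M, "W_att")
  check_matrix(W_agg, M, M, "W_agg")
  stopifnot(is.list(W_k), length(W_k) >= 1, !is.null(names(W_k)))
  for (p in names(W_k)) check_matrix(W_k[[p]], M, M, paste0("W_k[", p, "]"))
  structure(list(W_init = W_init, W_k = W_k, W_att = W_att, W_agg = W_agg),
            class = "attention_params")
}

#' Alternative-aggregation parameters
#'
#' @param mode One of `"concat"`, `"sum"`, `"max"`.
#' @param W The weight matrix of the chosen mode: `[M x (M * n_paths)]` for
#'   concat, `[M x M]` otherwise.
#' @param n_paths Number of enabled paths.
#' @return List of class `alt_agg_params`.
#' @export
alt_agg_params <- function(mode, W, n_paths) {
  mode <- match.arg(mode, c("concat", "sum", "max"))
  M <- nrow(W)
  if (mode == "concat") check_matrix(W, M, M * n_paths, "W_concat")
  else check_matrix(W, M, M, paste0("W_", mode))
  structure(list(mode = mode, W = W, n_paths = as.integer(n_paths)),
            class = "alt_agg_params")
}

check_paths_present <- function(H_paths, wanted) {
  missing <- setdiff(wanted, names(H_paths))
  if (length(missing))
    stop(sprintf("path feature(s) missing: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
}

#' Attention scores per atom and path
#'
#' `e_i^p = W_att (relu(H_i^init W_init) || relu(H_i^p W_p))`.
#'
#' @param H_init `[N x M]` initial atom features.
#' @param H_paths Named list of `[N x M]` per-path feature matrices.
#' @param params [attention_params()].
#' @return `[N x P]` matrix of scores, columns named by path.
#' @export
attention_scores <- function(H_init, H_paths, params) {
  check_paths_present(H_paths, names(params$W_k))
  paths <- names(params$W_k)
  M <- nrow(params$W_init)
  U <- relu(H_init %*% params$W_init)
  a <- params$W_att[1, seq_len(M)]
  b <- params$W_att[1, M + seq_len(M)]
  e <- sapply(paths, function(p) {
    V <- relu(H_paths[[p]] %*% params$W_k[[p]])
    drop(U %*% a + V %*% b)
  })
  e <- matrix(e, nrow = nrow(H_init), dimnames = list(NULL, paths))
  if (!all(is.finite(e))) stop("attention scores are not finite", call. = FALSE)
  e
}

#' Softmax attention weights over paths
#'
#' Row-wise softmax of the score matrix: each atom's weights over the
#' enabled paths sum to one.
#'
#' @param e `[N x P]` score matrix from [attention_scores()].
#' @return `[N x P]` matrix of weights in (0, 1), rows summing to 1.
#' @export
attention_weights <- function(e) {
  stopifnot(is.matrix(e), all(is.finite(e)))
  z <- exp(e - apply(e, 1, max))
  z / rowSums(z)
}

#' Attention aggregation of path features
#'
#' `H_i = relu(W_agg sum_p alpha_i^p H_i^p)`.
#'
#' @param H_paths Named list of `[N x M]` per-path features.
#' @param alpha `[N x P]` attention weights; rows must sum to 1.
#' @param params [attention_params()].
#' @return `[N x M]` aggregated feature matrix, elementwise nonnegative.
#' @export
aggregate_attention <- function(H_paths, alpha, params) {
  paths <- colnames(alpha) %||% names(params$W_k)
  check_paths_present(H_paths, paths)
  if (max(abs(rowSums(alpha) - 1)) > 1e-6)
    stop("alpha rows must sum to 1", call. = FALSE)
  N <- nrow(alpha); M <- nrow(params$W_agg)
  S <- matrix(0, N, M)
  for (k in seq_along(paths))
    S <- S + alpha[, k] * H_paths[[paths[k]]]
  relu(S %*% t(params$W_agg))
}

#' Concatenation, sum, or maximum aggregation
#'
#' `concat`: `relu(W (H^1 || ... || H^P))`; `sum`: `relu(W sum_p H^p)`;
#' `max`: `relu(W max_p H^p)` (elementwise maximum).
#'
#' @param H_paths Named list of `[N x M]` per-path features (order defines
#'   the concatenation order).
#' @param params [alt_agg_params()].
#' @return `[N x M]` aggregated feature matrix.
#' @export
aggregate_alt <- function(H_paths, params) {
  P <- length(H_paths)
  if (P != params$n_paths)
    stop(sprintf("aggregator built for %d paths, given %d",
                 params$n_paths, P), call. = FALSE)
  X <- switch(params$mode,
    concat = do.call(cbind, H_paths),
    sum = Reduce(`+`, H_paths),
    max = Reduce(pmax, H_paths))
  relu(X %*% t(params$W))
}

# ---- internal forward/backward used by the model ----

attention_agg_fwd <- function(H_init, H_paths, par) {
  paths <- names(par$W_k)
  check_paths_present(H_paths, paths)
  M <- nrow(par$W_init)
  N <- nrow(H_init)
  ZU <- H_init %*% par$W_init
  U <- relu(ZU)
  a <- par$W_att[1, seq_len(M)]
  b <- par$W_att[1, M + seq_len(M)]
  ua <- drop(U %*% a)
  ZV <- lapply(paths, function(p) H_paths[[p]] %*% par$W_k[[p]])
  names(ZV) <- paths
  V <- lapply(ZV, relu)
  e <- sapply(paths, function(p) ua + drop(V[[p]] %*% b))
  e <- matrix(e, nrow = N, dimnames = list(NULL, paths))
  alpha <- attention_weights(e)
  S <- matrix(0, N, M)
  for (k in seq_along(paths))
    S <- S + alpha[, k] * H_paths[[paths[k]]]
  Z2 <- S %*% t(par$W_agg)
  list(H = relu(Z2), alpha = alpha,
       cache = list(H_init = H_init, H_paths = H_paths, U = U, mU = ZU > 0,
                    V = V, mV = lapply(ZV, function(z) z > 0),
                    alpha = alpha, S = S, m2 = Z2 > 0, a = a, b = b,
                    paths = paths))
}

attention_agg_bwd <- function(dH, cache, par) {
  paths <- cache$paths
  M <- ncol(dH)
  dZ2 <- dH * cache$m2
  gW_agg <- t(dZ2) %*% cache$S
  dS <- dZ2 %*% par$W_agg
  alpha <- cache$alpha
  # d alpha and the alpha-weighted branch of dH_paths
  dalpha <- sapply(paths, function(p) rowSums(dS * cache$H_paths[[p]]))
  dalpha <- matrix(dalpha, nrow = nrow(dS))
  # softmax jacobian, rowwise
  de <- alpha * (dalpha - rowSums(alpha * dalpha))
  dH_paths <- lapply(seq_along(paths), function(k)
    alpha[, k] * dS)
  names(dH_paths) <- paths
  # scores: e_i^p = sum(a * U_i) + sum(b * V_i^p)
  de_rowsum <- rowSums(de)
  ga <- drop(t(cache$U) %*% de_rowsum)
  gb <- numeric(M)
  gW_k <- list()
  for (k in seq_along(paths)) {
    p <- paths[k]
    gb <- gb + drop(t(cache$V[[p]]) %*% de[, k])
    dV <- de[, k] %o% cache$b
    dZV <- dV * cache$mV[[p]]
    gW_k[[p]] <- t(cache$H_paths[[p]]) %*% dZV
    dH_paths[[p]] <- dH_paths[[p]] + dZV %*% t(par$W_k[[p]])
  }
  dU <- de_rowsum %o% cache$a
  dZU <- dU * cache$mU
  gW_init <- t(cache$H_init) %*% dZU
  gW_att <- matrix(c(ga, gb), 1)
  list(dH_paths = dH_paths,
       grads = list(W_init = gW_init, W_k = gW_k, W_att = gW_att,
                    W_agg = gW_agg))
}

alt_agg_fwd <- function(H_paths, par) {
  X <- switch(par$mode,
    concat = do.call(cbind, H_paths),
    sum = Reduce(`+`, H_paths),
    max = Reduce(pmax, H_paths))
  Z <- X %*% t(par$W)
  cache <- list(X = X, m = Z > 0, paths = names(H_paths))
  if (par$mode == "max") {
    # which path attains the max, per element (first of ties)
    amax <- matrix(1L, nrow(X), ncol(X))
    cur <- H_paths[[1]]
    for (k in seq_along(H_paths)[-1]) {
      upd <- H_paths[[k]] > cur
      amax[upd] <- k
      cur <- pmax(cur, H_paths[[k]])
    }
    cache$amax <- amax
  }
  list(H = relu(Z), cache = cache)
}

alt_agg_bwd <- function(dH, cache, par) {
  paths <- cache$paths
  M <- ncol(dH)
  dZ <- dH * cache$m
  gW <- t(dZ) %*% cache$X
  dX <- dZ %*% par$W
  dH_paths <- switch(par$mode,
    concat = {
      out <- lapply(seq_along(paths), function(k)
        dX[, (k - 1) * M + seq_len(M), drop = FALSE])
      names(out) <- paths
      out
    },
    sum = {
      out <- lapply(paths, function(p) dX)
      names(out) <- paths
      out
    },
    max = {
      out <- lapply(seq_along(paths), function(k)
        dX * (cache$amax == k))
      names(out) <- paths
      out
    })
  list(dH_paths = dH_paths, grads = list(W = gW))
}
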