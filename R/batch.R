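# Minibatch execution. A batch of molecular graphs is merged into one
# block-diagonal "super graph": atom features are stacked, pair lists are
# concatenated with index offsets, and a graph-id vector drives the
# per-molecule readout. Because the path layers only ever touch
# within-graph pairs, they run unchanged on the merged structure, turning
# sixteen small matrix products into one large one per layer.

build_batch <- function(graphs) {
  B <- length(graphs)
  ns <- vapply(graphs, `[[`, 0L, "n_atoms")
  offset <- cumsum(c(0L, ns[-B]))
  H0 <- do.call(rbind, lapply(graphs, `[[`, "H_init"))
  pis <- vector("list", B); pjs <- vector("list", B)
  chans <- vector("list", B); ss <- vector("list", B)
  has_coords <- TRUE
  for (k in seq_len(B)) {
    gc <- graphs[[k]]$cache
    pis[[k]] <- gc$pi + offset[k]
    pjs[[k]] <- gc$pj + offset[k]
    chans[[k]] <- gc$chan
    if (is.null(gc$s)) has_coords <- FALSE else ss[[k]] <- gc$s
  }
  gc <- list(n = sum(ns), K = length(unlist(pis)),
             pi = unlist(pis), pj = unlist(pjs), chan = unlist(chans),
             s = if (has_coords) unlist(ss))
  list(B = B, gc = gc, H0 = H0, gid = rep.int(seq_len(B), ns), ns = ns)
}

# Forward over a merged batch with caches kept; mirrors forward_cached().
batch_forward_cached <- function(model, batch) {
  cfg <- model$config
  if ("3d" %in% cfg$paths && is.null(batch$gc$s))
    stop("model has the 3d path enabled but a graph has no coordinates",
         call. = FALSE)
  streams <- list(); caches <- list()
  for (p in cfg$paths) {
    H <- batch$H0
    caches[[p]] <- vector("list", cfg$n_layers)
    fwd <- path_fwd(p)
    for (t in seq_len(cfg$n_layers)) {
      res <- fwd(H, batch$gc, layer_par(model, p, t))
      H <- res$H
      caches[[p]][[t]] <- res$cache
    }
    streams[[p]] <- H
  }
  alpha <- NULL; agg_cache <- NULL
  if (length(cfg$paths) == 1) {
    Hagg <- streams[[1]]
  } else if (cfg$aggregation == "attention") {
    res <- attention_agg_fwd(batch$H0, streams, agg_par(model))
    Hagg <- res$H; alpha <- res$alpha; agg_cache <- res$cache
  } else {
    res <- alt_agg_fwd(streams, agg_par(model))
    Hagg <- res$H; agg_cache <- res$cache
  }
  G <- rowsum0(Hagg, batch$gid)                      # [B x M] molecular vectors
  raw <- drop(G %*% t(model$params[["head.W_fc"]])) + model$params[["head.b_fc"]]
  list(raw = raw, alpha = alpha, G = G, streams = streams, caches = caches,
       agg_cache = agg_cache)
}

loss_and_draw <- function(raw, targets, loss) {
  n <- length(targets)
  if (loss == "mse") {
    list(loss = mean((raw - targets)^2), draw = 2 * (raw - targets) / n)
  } else {
    p <- stats::plogis(raw)
    eps <- 1e-12
    list(loss = -mean(targets * log(p + eps) + (1 - targets) * log(1 - p + eps)),
         draw = (p - targets) / n)
  }
}

# Gradients of the aggregation + head part, given dHagg upstream already
# formed; shared by the full backward and the stage-2 (frozen paths) fit.
agg_head_bwd <- function(model, batch, fw, draw) {
  cfg <- model$config
  grads <- list()
  grads[["head.W_fc"]] <- matrix(drop(crossprod(draw, fw$G)), 1)
  grads[["head.b_fc"]] <- sum(draw)
  dg <- draw %o% as.numeric(model$params[["head.W_fc"]])   # [B x M]
  dHagg <- dg[batch$gid, , drop = FALSE]
  dH_paths <- NULL
  if (length(cfg$paths) == 1) {
    dH_paths <- stats::setNames(list(dHagg), cfg$paths)
  } else if (cfg$aggregation == "attention") {
    ab <- attention_agg_bwd(dHagg, fw$agg_cache, agg_par(model))
    dH_paths <- ab$dH_paths
    grads[["agg.W_init"]] <- ab$grads$W_init
    grads[["agg.W_att"]] <- ab$grads$W_att
    grads[["agg.W_agg"]] <- ab$grads$W_agg
    for (p in names(ab$grads$W_k))
      grads[[paste0("agg.W_k.", p)]] <- ab$grads$W_k[[p]]
  } else {
    ab <- alt_agg_bwd(dHagg, fw$agg_cache, agg_par(model))
    dH_paths <- ab$dH_paths
    grads[["agg.W"]] <- ab$grads$W
  }
  list(grads = grads, dH_paths = dH_paths)
}

# Mean loss and gradients over a batch of graphs (all trainable groups).
batch_loss_grad <- function(model, batch, targets, loss = "mse") {
  cfg <- model$config
  fw <- batch_forward_cached(model, batch)
  ld <- loss_and_draw(fw$raw, targets, loss)
  top <- agg_head_bwd(model, batch, fw, ld$draw)
  grads <- top$grads
  for (p in cfg$paths) {
    bwd <- path_bwd(p)
    dH <- top$dH_paths[[p]]
    for (t in rev(seq_len(cfg$n_layers))) {
      res <- bwd(dH, fw$caches[[p]][[t]], layer_par(model, p, t))
      dH <- res$dH
      grads <- acc_grads(grads,
                         prefix_names(res$grads, paste(p, t, sep = ".")))
    }
  }
  list(loss = ld$loss, grads = grads, raw = fw$raw)
}

# Stage-2 variant: per-path final features are fixed inputs; only the
# aggregation and head receive gradients.
batch_agghead_grad <- function(model, H0, streams, gid, targets, loss) {
  cfg <- model$config
  alpha <- NULL
  if (length(cfg$paths) == 1) {
    Hagg <- streams[[1]]; agg_cache <- NULL
  } else if (cfg$aggregation == "attention") {
    res <- attention_agg_fwd(H0, streams, agg_par(model))
    Hagg <- res$H; agg_cache <- res$cache
  } else {
    res <- alt_agg_fwd(streams, agg_par(model))
    Hagg <- res$H; agg_cache <- res$cache
  }
  G <- rowsum0(Hagg, gid)
  raw <- drop(G %*% t(model$params[["head.W_fc"]])) + model$params[["head.b_fc"]]
  ld <- loss_and_draw(raw, targets, loss)
  top <- agg_head_bwd(model, list(gid = gid),
                      list(G = G, agg_cache = agg_cache), ld$draw)
  list(loss = ld$loss, grads = top$grads, raw = raw)
}
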