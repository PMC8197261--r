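#' Model configuration
#'
#' @param feature_dim Feature width M kept through all layers (default 60,
#'   the width of the initial atom features; the first layer consumes
#'   `H_init` directly, so this must match the featurization width unless
#'   you supply your own features).
#' @param n_layers Number of stacked update layers T per path (default 2).
#' @param paths Nonempty subset of `c("node", "edge", "3d")`.
#' @param aggregation `"attention"`, `"concat"`, `"sum"` or `"max"`.
#'   Irrelevant (identity pass-through) when a single path is enabled.
#' @param aggregate_placement `"final"` (each path evolves its own stream
#'   for T layers, aggregation happens once before readout; default) or
#'   `"every_layer"` (streams are merged after every layer).
#' @param edge_mode `"learned"` (edge channel weights trained, warm-started
#'   at 0.1 x the categorical values) or `"fixed"` (categorical values
#'   1..5, not trained).
#' @param include_self_3d Keep the atom's own feature in the 3D update?
#' @param task `"regression"` or `"classification"`.
#' @param seed Integer seed controlling parameter initialisation.
#' @return List of class `mpgcn_config`.
#' @export
model_config <- function(feature_dim = 60L, n_layers = 2L,
                         paths = c("node", "edge", "3d"),
                         aggregation = c("attention", "concat", "sum", "max"),
                         aggregate_placement = c("final", "every_layer"),
                         edge_mode = c("learned", "fixed"),
                         include_self_3d = TRUE,
                         task = c("regression", "classification"),
                         seed = 1L) {
  if (!length(paths)) stop("at least one path must be enabled", call. = FALSE)
  paths <- match.arg(paths, c("node", "edge", "3d"), several.ok = TRUE)
  structure(list(
    feature_dim = as.integer(feature_dim),
    n_layers = as.integer(n_layers),
    paths = paths,
    aggregation = match.arg(aggregation),
    aggregate_placement = match.arg(aggregate_placement),
    edge_mode = match.arg(edge_mode),
    include_self_3d = isTRUE(include_self_3d),
    task = match.arg(task),
    seed = as.integer(seed)
  ), class = "mpgcn_config")
}

# Flat parameter tables keyed "group.layer.name" ("node.1.W_np",
# "agg.W_att", "head.W_fc", ...). Everything downstream (Adam, freezing,
# checkpoints, counting) operates on this flat view.
init_params <- function(config) {
  M <- config$feature_dim
  T_ <- config$n_layers
  params <- list()
  trainable <- character()
  add <- function(name, value, train = TRUE) {
    params[[name]] <<- value
    if (train) trainable <<- c(trainable, name)
  }
  for (p in config$paths) {
    for (t in seq_len(T_)) {
      key <- function(nm) paste(p, t, nm, sep = ".")
      if (p == "node") {
        add(key("W_np"), glorot(M, 2 * M)); add(key("B_np"), numeric(M))
        add(key("W_n"), glorot(M, M)); add(key("B_n"), numeric(M))
      } else if (p == "edge") {
        add(key("W_ep"), glorot(M, 2 * M)); add(key("B_ep"), numeric(M))
        add(key("W_e"), glorot(M, M)); add(key("B_e"), numeric(M))
        if (config$edge_mode == "fixed") {
          add(key("w"), as.numeric(1:5), train = FALSE)
          add(key("c"), 0, train = FALSE)
        } else {
          add(key("w"), 0.1 * (1:5))
          add(key("c"), 0)
        }
      } else {
        add(key("W_tp"), glorot(M, 2 * M)); add(key("B_tp"), numeric(M))
        add(key("W_tq"), glorot(M, M)); add(key("B_tq"), numeric(M))
        if (config$include_self_3d) add(key("W_t"), glorot(M, 2 * M))
        else add(key("W_ns"), glorot(M, M))
      }
    }
  }
  if (length(config$paths) > 1) {
    if (config$aggregation == "attention") {
      add("agg.W_init", glorot(M, M))
      for (p in config$paths) add(paste0("agg.W_k.", p), glorot(M, M))
      add("agg.W_att", glorot(1, 2 * M))
      add("agg.W_agg", glorot(M, M))
    } else if (config$aggregation == "concat") {
      add("agg.W", glorot(M, M * length(config$paths)))
    } else {
      add("agg.W", glorot(M, M))
    }
  }
  add("head.W_fc", glorot(1, M))
  add("head.b_fc", 0)
  list(params = params, trainable = trainable)
}

#' Build a multi-path model
#'
#' Parameter initialisation is deterministic given `config$seed`: dense
#' weights are Glorot-uniform, biases zero, edge channel weights start at
#' the categorical values scaled by 0.1 (learned mode) or exactly 1..5
#' (fixed mode, excluded from training).
#'
#' @param config A [model_config()].
#' @return Object of class `mpgcn_model`.
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "mpgcn_config"))
  ini <- with_seed(config$seed, init_params(config))
  structure(list(config = config, params = ini$params,
                 trainable = ini$trainable, scaler = NULL),
            class = "mpgcn_model")
}

# Plain-list layer parameter views consumed by the path forward/backwards.
layer_par <- function(model, path, t) {
  P <- model$params
  k <- function(nm) P[[paste(path, t, nm, sep = ".")]]
  if (path == "node") {
    list(W_np = k("W_np"), B_np = k("B_np"), W_n = k("W_n"), B_n = k("B_n"))
  } else if (path == "edge") {
    list(W_ep = k("W_ep"), B_ep = k("B_ep"), W_e = k("W_e"), B_e = k("B_e"),
         w = k("w"), c = k("c"),
         fixed_mode = model$config$edge_mode == "fixed")
  } else {
    list(W_tp = k("W_tp"), B_tp = k("B_tp"), W_tq = k("W_tq"),
         B_tq = k("B_tq"), W_t = k("W_t"), W_ns = k("W_ns"),
         include_self = model$config$include_self_3d)
  }
}

agg_par <- function(model) {
  cfg <- model$config
  if (length(cfg$paths) <= 1) return(NULL)
  P <- model$params
  if (cfg$aggregation == "attention") {
    W_k <- lapply(cfg$paths, function(p) P[[paste0("agg.W_k.", p)]])
    names(W_k) <- cfg$paths
    list(W_init = P[["agg.W_init"]], W_k = W_k, W_att = P[["agg.W_att"]],
         W_agg = P[["agg.W_agg"]])
  } else {
    list(mode = cfg$aggregation, W = P[["agg.W"]],
         n_paths = length(cfg$paths))
  }
}

# Full forward pass with caches retained for backprop (placement "final").
forward_cached <- function(model, graph) {
  cfg <- model$config
  M <- cfg$feature_dim
  H0 <- graph$H_init
  if (ncol(H0) != M)
    stop_shape("graph features", c(graph$n_atoms, M), dim(H0))
  gc <- graph$cache
  if ("3d" %in% cfg$paths && is.null(gc$s))
    stop("model has the 3d path enabled but the graph has no coordinates",
         call. = FALSE)
  streams <- list(); caches <- list()
  for (p in cfg$paths) {
    H <- H0
    caches[[p]] <- vector("list", cfg$n_layers)
    fwd <- path_fwd(p)
    for (t in seq_len(cfg$n_layers)) {
      res <- fwd(H, gc, layer_par(model, p, t))
      H <- res$H
      caches[[p]][[t]] <- res$cache
    }
    streams[[p]] <- H
  }
  alpha <- NULL; agg_cache <- NULL
  if (length(cfg$paths) == 1) {
    Hagg <- streams[[1]]
  } else if (cfg$aggregation == "attention") {
    res <- attention_agg_fwd(H0, streams, agg_par(model))
    Hagg <- res$H; alpha <- res$alpha; agg_cache <- res$cache
  } else {
    res <- alt_agg_fwd(streams, agg_par(model))
    Hagg <- res$H; agg_cache <- res$cache
  }
  g <- colSums(Hagg)
  raw <- sum(model$params[["head.W_fc"]] * g) + model$params[["head.b_fc"]]
  list(raw = raw, alpha = alpha, g = g, Hagg = Hagg, streams = streams,
       caches = caches, agg_cache = agg_cache, n = graph$n_atoms)
}

forward_every_layer <- function(model, graph) {
  cfg <- model$config
  H0 <- graph$H_init
  gc <- graph$cache
  H <- H0
  alpha <- NULL
  for (t in seq_len(cfg$n_layers)) {
    streams <- list()
    for (p in cfg$paths)
      streams[[p]] <- path_fwd(p)(H, gc, layer_par(model, p, t))$H
    if (length(cfg$paths) == 1) {
      H <- streams[[1]]
    } else if (cfg$aggregation == "attention") {
      res <- attention_agg_fwd(H0, streams, agg_par(model))
      H <- res$H; alpha <- res$alpha
    } else {
      H <- alt_agg_fwd(streams, agg_par(model))$H
    }
  }
  g <- colSums(H)
  raw <- sum(model$params[["head.W_fc"]] * g) + model$params[["head.b_fc"]]
  list(raw = raw, alpha = alpha)
}

#' Forward pass: predict one molecule
#'
#' Runs every enabled path for T layers starting from the initial atom
#' features, merges the final per-path features (default placement), sums
#' atom features dimension-wise into a molecular vector and applies the
#' affine head. For classification the raw output is returned; apply
#' `stats::plogis()` (or `predict(..., type = "prob")`) for a probability.
#'
#' @param model An [build_model()] object.
#' @param graph A [molecular_graph()].
#' @return Numeric scalar prediction. When attention aggregation is active
#'   the per-atom attention weights are attached as attribute `"alpha"`
#'   (`[N x P]`, columns named by path).
#' @export
forward <- function(model, graph) {
  stopifnot(inherits(model, "mpgcn_model"),
            inherits(graph, "molecular_graph"))
  res <- if (model$config$aggregate_placement == "final")
    forward_cached(model, graph)
  else forward_every_layer(model, graph)
  out <- res$raw
  if (!is.null(res$alpha)) attr(out, "alpha") <- res$alpha
  out
}

model_predict_raw <- function(model, graphs) {
  if (!length(graphs)) return(numeric())
  if (model$config$aggregate_placement == "final")
    batch_forward_cached(model, build_batch(graphs))$raw
  else
    vapply(graphs, function(g) as.numeric(forward(model, g))[1], 0)
}

#' Count model parameters
#'
#' Exact count of trainable scalar parameters, with a per-group breakdown
#' (each path, the aggregator, the head) attached as attribute
#' `"breakdown"`. Fixed-mode edge values are excluded: they are constants,
#' not parameters.
#'
#' @param model An `mpgcn_model`.
#' @return Integer count.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "mpgcn_model"))
  sizes <- vapply(model$params[model$trainable], length, 0L)
  group <- sub("\\..*$", "", names(sizes))
  breakdown <- vapply(split(sizes, group), sum, 0L)
  structure(sum(sizes), breakdown = breakdown)
}

#' @export
print.mpgcn_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<mpgcn_model: paths=%s, T=%d, M=%d, agg=%s, task=%s>\n",
              paste(cfg$paths, collapse = "+"), cfg$n_layers,
              cfg$feature_dim,
              if (length(cfg$paths) > 1) cfg$aggregation else "none",
              cfg$task))
  n <- count_parameters(x)
  bd <- attr(n, "breakdown")
  cat(sprintf("  %d trainable parameters (%s)\n", n,
              paste(sprintf("%s=%d", names(bd), bd), collapse = ", ")))
  invisible(x)
}

# ---- checkpointing ----

num_out <- function(x) sprintf("%.17g", x)

#' Save a model checkpoint
#'
#' Single-file JSON archive embedding the full configuration, the
#' featurization layout version, the target scaler (if any) and every
#' parameter array. Numbers are stored at 17 significant digits so a
#' reloaded model reproduces predictions exactly.
#'
#' @param model An `mpgcn_model`.
#' @param path Output file.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "mpgcn_model"))
  obj <- list(
    format = "mpgcn-checkpoint-1",
    feature_layout = FEATURE_LAYOUT,
    config = unclass(model$config),
    trainable = model$trainable,
    scaler = if (!is.null(model$scaler))
      list(mean = num_out(model$scaler$mean), sd = num_out(model$scaler$sd)),
    params = lapply(model$params, function(p) list(
      dim = if (is.matrix(p)) dim(p) else length(p),
      data = num_out(as.numeric(p))))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path File written by [save_checkpoint()].
#' @return An `mpgcn_model` whose predictions are identical to the saved
#'   model's.
#' @export
load_checkpoint <- function(path) {
  stopifnot(file.exists(path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "mpgcn-checkpoint-1"))
    stop("not an mpgcn checkpoint", call. = FALSE)
  if (!identical(obj$feature_layout, FEATURE_LAYOUT))
    stop(sprintf("featurization layout mismatch: checkpoint '%s', package '%s'",
                 obj$feature_layout, FEATURE_LAYOUT), call. = FALSE)
  cfg <- do.call(model_config, obj$config[setdiff(names(obj$config), NULL)])
  skeleton <- build_model(cfg)
  if (!setequal(names(skeleton$params), names(obj$params)))
    stop("checkpoint parameter names do not match its configuration",
         call. = FALSE)
  params <- list()
  for (nm in names(skeleton$params)) {
    ref <- skeleton$params[[nm]]
    entry <- obj$params[[nm]]
    vals <- as.numeric(entry$data)
    if (length(vals) != length(ref))
      stop(sprintf("checkpoint parameter '%s' has %d values, expected %d ",
                   nm, length(vals), length(ref)), call. = FALSE)
    params[[nm]] <- if (is.matrix(ref))
      matrix(vals, nrow(ref), ncol(ref)) else vals
  }
  model <- skeleton
  model$params <- params
  if (!is.null(obj$scaler))
    model$scaler <- list(mean = as.numeric(obj$scaler$mean),
                         sd = as.numeric(obj$scaler$sd))
  model
}
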