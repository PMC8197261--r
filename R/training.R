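#' Training configuration
#'
#' Defaults follow the reference protocol: minibatches of 16 molecules,
#' Adam at learning rate 1e-3, MSE loss, early stopping once ten successive
#' epochs each improve the running best monitored loss by less than 1e-4.
#'
#' @param batch_size Minibatch size (the incomplete final batch is used).
#' @param optimizer `"adam"` or `"sgd"`.
#' @param learning_rate Step size.
#' @param patience Successive low-improvement epochs before stopping.
#' @param min_delta Minimum improvement of the running best to count.
#' @param max_epochs Hard epoch cap per stage.
#' @param monitored_loss `"validation"` or `"training"`.
#' @param loss `"mse"` (default, also for 0/1 classification targets) or
#'   `"bce"`.
#' @param standardize Z-score regression targets from the training split
#'   (inverted at evaluation)?
#' @param seed Seed for batch shuffling.
#' @return List of class `train_config`.
#' @export
train_config <- function(batch_size = 16L, optimizer = c("adam", "sgd"),
                         learning_rate = 1e-3, patience = 10L,
                         min_delta = 1e-4, max_epochs = 500L,
                         monitored_loss = c("validation", "training"),
                         loss = c("mse", "bce"), standardize = TRUE,
                         seed = 1L) {
  stopifnot(patience >= 1, min_delta >= 0, batch_size >= 1, max_epochs >= 1)
  structure(list(
    batch_size = as.integer(batch_size), optimizer = match.arg(optimizer),
    learning_rate = learning_rate, patience = as.integer(patience),
    min_delta = min_delta, max_epochs = as.integer(max_epochs),
    monitored_loss = match.arg(monitored_loss), loss = match.arg(loss),
    standardize = isTRUE(standardize), seed = as.integer(seed)
  ), class = "train_config")
}

#' Split/trial specification
#'
#' @param fractions Train/validation/test fractions summing to 1
#'   (default 0.8/0.1/0.1).
#' @param n_trials Number of repeated random splits (default 10).
#' @param base_seed Trial t draws its permutation from `base_seed + t`.
#' @return List of class `split_spec`.
#' @export
split_spec <- function(fractions = c(0.8, 0.1, 0.1), n_trials = 10L,
                       base_seed = 1L) {
  stopifnot(length(fractions) == 3, abs(sum(fractions) - 1) < 1e-9,
            all(fractions > 0))
  structure(list(fractions = fractions, n_trials = as.integer(n_trials),
                 base_seed = as.integer(base_seed)), class = "split_spec")
}

#' Split records into train/validation/test
#'
#' Sizes are `floor(f1 n)`, `floor(f2 n)` and the remainder; the
#' permutation is drawn from `base_seed + trial`, so the same spec and
#' trial always reproduce the same split.
#'
#' @param records List of records.
#' @param spec A [split_spec()].
#' @param trial Trial index.
#' @return List with elements `train`, `valid`, `test` and an `indices`
#'   attribute.
#' @export
split_dataset <- function(records, spec, trial = 1L) {
  n <- length(records)
  if (n < 10) stop("need at least 10 records to split", call. = FALSE)
  perm <- with_seed(spec$base_seed + trial, sample.int(n))
  n_train <- floor(spec$fractions[1] * n)
  n_valid <- floor(spec$fractions[2] * n)
  idx <- list(train = perm[seq_len(n_train)],
              valid = perm[n_train + seq_len(n_valid)],
              test = perm[(n_train + n_valid + 1):n])
  structure(list(train = records[idx$train], valid = records[idx$valid],
                 test = records[idx$test]), indices = idx)
}

#' Mean squared error
#'
#' @param pred,target Equal-length numeric vectors.
#' @return `mean((pred - target)^2)`.
#' @export
mse_loss <- function(pred, target) {
  if (length(pred) == 0) stop("empty input", call. = FALSE)
  if (length(pred) != length(target))
    stop("pred and target must have equal length", call. = FALSE)
  mean((pred - target)^2)
}

#' Early-stopping rule
#'
#' Training stops once the last `patience` epochs each improved the running
#' best loss by less than `min_delta`, where the improvement at epoch e is
#' `best_before_e - loss_e`. The first epoch always counts as improving.
#'
#' @param loss_history Numeric vector of per-epoch monitored losses.
#' @param patience Number of successive low-improvement epochs required.
#' @param min_delta Improvement threshold.
#' @return Logical.
#' @export
should_stop <- function(loss_history, patience = 10L, min_delta = 1e-4) {
  L <- length(loss_history)
  if (L < patience + 1) return(FALSE)
  best_before <- c(Inf, cummin(loss_history)[-L])
  impr <- best_before - loss_history
  all(impr[(L - patience + 1):L] < min_delta)
}

# ---- optimizers ----

opt_init <- function(param_names) {
  list(t = 0L,
       m = stats::setNames(vector("list", length(param_names)), param_names),
       v = stats::setNames(vector("list", length(param_names)), param_names))
}

opt_step <- function(params, grads, state, update, tc) {
  lr <- tc$learning_rate
  if (tc$optimizer == "sgd") {
    for (nm in update) params[[nm]] <- params[[nm]] - lr * grads[[nm]]
    return(list(params = params, state = state))
  }
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  state$t <- state$t + 1L
  bc1 <- 1 - b1^state$t
  bc2 <- 1 - b2^state$t
  for (nm in update) {
    g <- grads[[nm]]
    if (is.null(g)) next
    m <- state$m[[nm]]; v <- state$v[[nm]]
    if (is.null(m)) { m <- g * 0; v <- g * 0 }
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g * g
    state$m[[nm]] <- m; state$v[[nm]] <- v
    params[[nm]] <- params[[nm]] - lr * (m / bc1) / (sqrt(v / bc2) + eps)
  }
  list(params = params, state = state)
}

# ---- generic minibatch loop ----
#
# modelish: anything with $params; grad_fn(modelish, idx) -> list(loss,
# grads) over the training subset idx; eval_fn(modelish) -> validation
# loss (or NULL when monitoring training loss).
train_loop <- function(modelish, n_train, tc, update, grad_fn, eval_fn,
                       seed, stage) {
  state <- opt_init(update)
  train_hist <- numeric()
  valid_hist <- numeric()
  stop_reason <- "max_epochs"
  with_seed(seed, {
    for (epoch in seq_len(tc$max_epochs)) {
      idx <- sample.int(n_train)
      batches <- split(idx, ceiling(seq_along(idx) / tc$batch_size))
      tot <- 0
      for (bt in batches) {
        res <- grad_fn(modelish, bt)
        if (!is.finite(res$loss))
          stop(sprintf("training diverged (non-finite loss) at epoch %d",
                       epoch), call. = FALSE)
        tot <- tot + res$loss * length(bt)
        st <- opt_step(modelish$params, res$grads, state, update, tc)
        modelish$params <- st$params
        state <- st$state
      }
      train_hist[epoch] <- tot / n_train
      monitored <- train_hist
      if (!is.null(eval_fn)) {
        valid_hist[epoch] <- eval_fn(modelish)
        if (tc$monitored_loss == "validation") monitored <- valid_hist
      }
      if (should_stop(monitored, tc$patience, tc$min_delta)) {
        stop_reason <- "early_stop"
        break
      }
    }
  })
  log <- list(stage = stage, train_loss = train_hist,
              valid_loss = if (length(valid_hist)) valid_hist,
              stop_epoch = length(train_hist), stop_reason = stop_reason,
              updated = update)
  list(modelish = modelish, log = log)
}

# Single-path submodel sharing the parent's path parameters plus a fresh
# temporary readout head (seeded from the parent seed and path index).
make_path_submodel <- function(model, path) {
  cfg <- model$config
  sub_cfg <- model_config(feature_dim = cfg$feature_dim,
                          n_layers = cfg$n_layers, paths = path,
                          aggregation = cfg$aggregation,
                          edge_mode = cfg$edge_mode,
                          include_self_3d = cfg$include_self_3d,
                          task = cfg$task,
                          seed = cfg$seed + match(path, c("node", "edge", "3d")))
  sub <- build_model(sub_cfg)
  shared <- grep(paste0("^", path, "\\."), names(model$params), value = TRUE)
  for (nm in shared) sub$params[[nm]] <- model$params[[nm]]
  sub
}

record_graphs <- function(records) lapply(records, `[[`, "graph")
record_targets <- function(records) vapply(records, `[[`, 0, "target")

#' Stage 1: train each path independently
#'
#' Every enabled path gets its own temporary sum-readout and affine head
#' and is trained on the target alone; aggregation parameters and the
#' final head are untouched. Temporary heads are recorded in the logs but
#' discarded.
#'
#' @param model An `mpgcn_model`.
#' @param train,valid Lists of records (`list(graph=, target=)`).
#' @param config A [train_config()].
#' @return List with the updated `model` and `logs` (one per path).
#' @export
train_stage1 <- function(model, train, valid, config) {
  stopifnot(inherits(model, "mpgcn_model"), inherits(config, "train_config"))
  gtrain <- record_graphs(train); ytrain <- record_targets(train)
  gvalid <- record_graphs(valid); yvalid <- record_targets(valid)
  logs <- list()
  heads <- list()
  vbatch <- if (length(gvalid)) build_batch(gvalid)
  for (p in model$config$paths) {
    sub <- make_path_submodel(model, p)
    update <- intersect(sub$trainable, names(sub$params))
    grad_fn <- function(ms, idx)
      batch_loss_grad(ms, build_batch(gtrain[idx]), ytrain[idx], config$loss)
    eval_fn <- if (length(gvalid)) function(ms) {
      raw <- batch_forward_cached(ms, vbatch)$raw
      loss_and_draw(raw, yvalid, config$loss)$loss
    }
    res <- train_loop(sub, length(gtrain), config, update, grad_fn, eval_fn,
                      seed = config$seed + match(p, c("node", "edge", "3d")),
                      stage = paste0("stage1:", p))
    sub <- res$modelish
    shared <- grep(paste0("^", p, "\\."), names(model$params), value = TRUE)
    for (nm in shared) model$params[[nm]] <- sub$params[[nm]]
    heads[[p]] <- sub$params[c("head.W_fc", "head.b_fc")]
    logs[[p]] <- res$log
  }
  list(model = model, logs = logs, temp_heads = heads)
}

#' Stage 2: train the aggregation layer and final head with paths frozen
#'
#' Path parameters are bitwise untouched (asserted after the run); only the
#' aggregation parameters and the final fully connected layer are updated,
#' under the same stopping rule as stage 1. Because the paths are frozen,
#' their output features are precomputed once per molecule.
#'
#' @inheritParams train_stage1
#' @return List with the updated `model` and the stage `log`.
#' @export
train_stage2 <- function(model, train, valid, config) {
  stopifnot(inherits(model, "mpgcn_model"), inherits(config, "train_config"))
  path_names <- grep("^(node|edge|3d)\\.", names(model$params), value = TRUE)
  frozen_before <- model$params[path_names]
  gtrain <- record_graphs(train); ytrain <- record_targets(train)
  gvalid <- record_graphs(valid); yvalid <- record_targets(valid)
  # paths are frozen: their output features are computed once, then reused
  tb <- build_batch(gtrain)
  Ftrain <- batch_forward_cached(model, tb)$streams
  rowidx <- split(seq_len(nrow(tb$H0)), tb$gid)
  vb <- if (length(gvalid)) build_batch(gvalid)
  Fvalid <- if (length(gvalid)) batch_forward_cached(model, vb)$streams
  update <- intersect(model$trainable,
                      grep("^(agg|head)\\.", names(model$params), value = TRUE))
  grad_fn <- function(ms, idx) {
    rows <- unlist(rowidx[idx], use.names = FALSE)
    streams <- lapply(Ftrain, function(Fp) Fp[rows, , drop = FALSE])
    batch_agghead_grad(ms, tb$H0[rows, , drop = FALSE], streams,
                       rep.int(seq_along(idx), tb$ns[idx]), ytrain[idx],
                       config$loss)
  }
  eval_fn <- if (length(gvalid)) function(ms)
    batch_agghead_grad(ms, vb$H0, Fvalid, vb$gid, yvalid, config$loss)$loss
  res <- train_loop(model, length(gtrain), config, update, grad_fn, eval_fn,
                    seed = config$seed + 100L, stage = "stage2")
  model <- res$modelish
  stopifnot(identical(model$params[path_names], frozen_before))
  list(model = model, log = res$log)
}

fit_scaler <- function(targets) {
  s <- stats::sd(targets)
  list(mean = mean(targets), sd = if (is.finite(s) && s > 0) s else 1)
}

scale_records <- function(records, scaler) {
  lapply(records, function(r) {
    r$target <- (r$target - scaler$mean) / scaler$sd
    r
  })
}

# Full two-stage fit on given train/valid records; returns the fitted model
# (with scaler attached for regression) and both logs.
fit_two_stage <- function(train, valid, model_config, train_config) {
  model <- build_model(model_config)
  scaler <- NULL
  if (model_config$task == "regression" && train_config$standardize) {
    scaler <- fit_scaler(record_targets(train))
    train <- scale_records(train, scaler)
    valid <- scale_records(valid, scaler)
  }
  s1 <- train_stage1(model, train, valid, train_config)
  s2 <- train_stage2(s1$model, train, valid, train_config)
  model <- s2$model
  model$scaler <- scaler
  list(model = model, logs = list(stage1 = s1$logs, stage2 = s2$log),
       temp_heads = s1$temp_heads)
}

# Model predictions on the original target scale (probabilities for
# classification).
predict_records <- function(model, records, type = c("response", "prob")) {
  type <- match.arg(type)
  raw <- model_predict_raw(model, record_graphs(records))
  if (model$config$task == "classification") {
    if (type == "prob" || type == "response") return(stats::plogis(raw))
  }
  if (!is.null(model$scaler)) raw <- raw * model$scaler$sd + model$scaler$mean
  raw
}

#' Run the repeated-split evaluation protocol
#'
#' For each trial: a fresh random split (seeded by `split$base_seed +
#' trial`), a fresh model (seeded by `model$seed + trial`), two-stage
#' training, and test-set metrics. Metrics are averaged over trials with
#' [aggregate_trials()].
#'
#' @param records List of records.
#' @param model_config A [model_config()].
#' @param train_config A [train_config()].
#' @param split A [split_spec()].
#' @return Object of class `mpgcn_trials`: list with `results` (per-trial),
#'   `mean`, `sd`.
#' @export
run_trials <- function(records, model_config, train_config,
                       split = split_spec()) {
  results <- vector("list", split$n_trials)
  for (trial in seq_len(split$n_trials)) {
    sp <- split_dataset(records, split, trial)
    mc <- model_config
    mc$seed <- model_config$seed + trial
    tc <- train_config
    tc$seed <- train_config$seed + trial
    fit <- tryCatch(
      fit_two_stage(sp$train, sp$valid, mc, tc),
      error = function(e) stop(sprintf("trial %d failed: %s", trial,
                                       conditionMessage(e)), call. = FALSE))
    ytest <- record_targets(sp$test)
    if (model_config$task == "regression") {
      pred <- predict_records(fit$model, sp$test)
      metrics <- c(mae = mae(pred, ytest))
    } else {
      prob <- predict_records(fit$model, sp$test, type = "prob")
      metrics <- unlist(classification_metrics(prob, ytest))
      if (length(unique(ytest)) == 2)
        metrics <- c(metrics, auc = roc_points(prob, ytest)$auc)
    }
    results[[trial]] <- list(trial = trial, task = model_config$task,
                             metrics = metrics, n_test = length(ytest))
  }
  agg <- aggregate_trials(results)
  structure(list(results = results, mean = agg$mean, sd = agg$sd),
            class = "mpgcn_trials")
}

#' @export
print.mpgcn_trials <- function(x, ...) {
  cat(sprintf("<mpgcn_trials: %d trial(s)>\n", length(x$results)))
  df <- data.frame(metric = names(x$mean), mean = as.numeric(x$mean),
                   sd = as.numeric(x$sd))
  print(df, row.names = FALSE)
  invisible(x)
}
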