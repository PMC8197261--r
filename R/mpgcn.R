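#' Fit a multi-path graph convolutional network
#'
#' The top-level fitting interface. Records are molecular graphs paired
#' with a numeric target (from [read_csv_dataset()], [read_sdf_dataset()]
#' or [make_dataset()]). A validation set is split off (or supplied), the
#' model is trained in two stages — each path independently with a
#' temporary head, then the aggregation layer and final head with the
#' paths frozen — and the fitted network is returned as a classed object
#' with the usual methods (`print`, `summary`, `coef`, `predict`, `plot`,
#' `residuals`).
#'
#' @param records List of `list(graph=, target=)` records.
#' @param model A [model_config()].
#' @param training A [train_config()].
#' @param valid Optional list of validation records; by default a fraction
#'   of `records` is held out.
#' @param valid_fraction Fraction held out when `valid` is `NULL`
#'   (default 0.1).
#' @return Object of class `mpgcn`.
#' @examples
#' \donttest{
#' recs <- make_dataset(synth_spec(n_molecules = 60, mode = "composition",
#'                                 seed = 7))
#' fit <- mpgcn(recs, model = model_config(paths = "node", n_layers = 1),
#'              training = train_config(max_epochs = 3))
#' predict(fit, recs[1:3])
#' }
#' @export
mpgcn <- function(records, model = model_config(),
                  training = train_config(), valid = NULL,
                  valid_fraction = 0.1) {
  stopifnot(length(records) >= 2, inherits(model, "mpgcn_config"),
            inherits(training, "train_config"))
  train <- records
  if (is.null(valid)) {
    n <- length(records)
    n_valid <- max(1L, floor(valid_fraction * n))
    idx <- with_seed(training$seed, sample.int(n, n_valid))
    valid <- records[idx]
    train <- records[-idx]
  }
  fit <- fit_two_stage(train, valid, model, training)
  fitted_vals <- predict_records(fit$model, train)
  structure(list(
    model = fit$model, logs = fit$logs, config = model, training = training,
    n_train = length(train), n_valid = length(valid),
    fitted = fitted_vals, target = record_targets(train),
    call = match.call()
  ), class = "mpgcn")
}

#' @export
print.mpgcn <- function(x, ...) {
  cat("Multi-path graph convolutional network\n")
  cat("Call: "); print(x$call)
  print(x$model)
  s2 <- x$logs$stage2
  cat(sprintf("  trained on %d molecules (+%d validation); stage 2 stopped after %d epoch(s) [%s]\n",
              x$n_train, x$n_valid, s2$stop_epoch, s2$stop_reason))
  invisible(x)
}

#' @export
summary.mpgcn <- function(object, ...) {
  res <- stats::residuals(object)
  out <- list(
    config = object$config,
    n_parameters = count_parameters(object$model),
    n_train = object$n_train, n_valid = object$n_valid,
    train_mae = mae(object$fitted, object$target),
    residual_summary = summary(res),
    stage1_epochs = vapply(object$logs$stage1, `[[`, 0L, "stop_epoch"),
    stage2_epochs = object$logs$stage2$stop_epoch
  )
  class(out) <- "summary.mpgcn"
  out
}

#' @export
print.summary.mpgcn <- function(x, ...) {
  cat(sprintf("mpgcn fit: paths=%s, T=%d, M=%d, %d parameters\n",
              paste(x$config$paths, collapse = "+"), x$config$n_layers,
              x$config$feature_dim, as.integer(x$n_parameters)))
  cat(sprintf("training molecules: %d (+%d validation)\n",
              x$n_train, x$n_valid))
  cat(sprintf("stage-1 epochs: %s; stage-2 epochs: %d\n",
              paste(sprintf("%s=%d", names(x$stage1_epochs),
                            x$stage1_epochs), collapse = ", "),
              x$stage2_epochs))
  cat(sprintf("training MAE: %.4f\n", x$train_mae))
  cat("residuals:\n")
  print(x$residual_summary)
  invisible(x)
}

#' Predict molecular properties from a fitted model
#'
#' @param object An `mpgcn` fit.
#' @param newdata List of records or of [molecular_graph()] objects.
#' @param type `"response"` (target scale; probabilities for a
#'   classification model) or `"prob"`.
#' @param ... Unused.
#' @return Numeric vector.
#' @export
predict.mpgcn <- function(object, newdata, type = c("response", "prob"),
                          ...) {
  type <- match.arg(type)
  recs <- lapply(newdata, function(r) {
    if (inherits(r, "molecular_graph")) list(graph = r, target = NA_real_)
    else r
  })
  predict_records(object$model, recs, type = type)
}

#' @export
residuals.mpgcn <- function(object, ...) {
  object$target - object$fitted
}

#' @export
coef.mpgcn <- function(object, ...) {
  p <- object$model$params[object$model$trainable]
  out <- unlist(lapply(names(p), function(nm) {
    v <- as.numeric(p[[nm]])
    stats::setNames(v, if (length(v) == 1) nm
                    else paste0(nm, "[", seq_along(v), "]"))
  }))
  out
}

#' Plot training loss curves
#'
#' One panel per stage-1 path plus the stage-2 aggregation/head stage;
#' training loss solid, validation loss dashed.
#'
#' @param x An `mpgcn` fit.
#' @param ... Passed to `matplot`.
#' @method plot mpgcn
#' @export
plot.mpgcn <- function(x, ...) {
  logs <- c(x$logs$stage1, list(stage2 = x$logs$stage2))
  old <- graphics::par(mfrow = c(1, length(logs)))
  on.exit(graphics::par(old))
  for (nm in names(logs)) {
    lg <- logs[[nm]]
    Y <- cbind(train = lg$train_loss,
               valid = lg$valid_loss %||% rep(NA, length(lg$train_loss)))
    graphics::matplot(Y, type = "l", lty = c(1, 2), col = c(1, 2),
                      xlab = "epoch", ylab = "loss",
                      main = if (nm == "stage2") "stage 2 (agg + head)"
                             else paste0("stage 1: ", nm, " path"), ...)
    graphics::legend("topright", c("train", "valid"), lty = c(1, 2),
                     col = c(1, 2), bty = "n")
  }
  invisible(x)
}
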