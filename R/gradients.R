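# Analytic gradients of the full forward pass + loss with respect to every
# trainable parameter, for the default ("final") aggregate placement.
# Verified against central finite differences in the test suite.

# Accumulate `add` into flat gradient table `acc` (names created on first use).
acc_grads <- function(acc, add) {
  for (nm in names(add)) {
    acc[[nm]] <- if (is.null(acc[[nm]])) add[[nm]] else acc[[nm]] + add[[nm]]
  }
  acc
}

prefix_names <- function(x, prefix) {
  names(x) <- paste(prefix, names(x), sep = ".")
  x
}

# Mean loss and mean gradients over a list of graphs.
#
# loss "mse": mean (raw - y)^2. loss "bce": binary cross-entropy of
# plogis(raw) against y in {0,1}.
model_loss_grad <- function(model, graphs, targets, loss = c("mse", "bce")) {
  loss <- match.arg(loss)
  if (model$config$aggregate_placement != "final")
    stop("gradient-based training supports the 'final' aggregate placement",
         call. = FALSE)
  n <- length(graphs)
  stopifnot(n >= 1, length(targets) == n)
  batch_loss_grad(model, build_batch(graphs), targets, loss)
}
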