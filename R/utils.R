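# Internal numeric helpers shared across the package.

# Rectified linear unit; sigma throughout the model.
relu <- function(x) {
  x[x < 0] <- 0
  x
}

# Run `code` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Glorot-uniform initialisation for a [nrow x ncol] weight matrix.
glorot <- function(nrow, ncol) {
  lim <- sqrt(6 / (nrow + ncol))
  matrix(stats::runif(nrow * ncol, -lim, lim), nrow, ncol)
}

# Add a length-M bias vector to every row of a [K x M] matrix without
# constructing an intermediate transpose (column-major recycling).
add_bias <- function(Z, b) {
  Z + rep(b, each = nrow(Z))
}

stop_shape <- function(what, expected, actual) {
  stop(sprintf("%s: expected %s, got %s", what,
               paste(expected, collapse = "x"),
               paste(actual, collapse = "x")), call. = FALSE)
}

check_matrix <- function(X, nrow, ncol, what) {
  if (!is.matrix(X) || nrow(X) != nrow || ncol(X) != ncol)
    stop_shape(what, c(nrow, ncol),
               if (is.matrix(X)) dim(X) else length(X))
  invisible(X)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# rowsum with the group rownames stripped (they would otherwise propagate
# into every feature matrix downstream).
rowsum0 <- function(X, group) {
  r <- rowsum(X, group)
  dimnames(r) <- NULL
  r
}
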