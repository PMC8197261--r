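# Synthetic molecular graphs with exactly known structure-property ground
# truth. Each task mode is informative for exactly one path: elemental
# composition for the node path, bond-type counts for the edge path, and
# mean pairwise distance for the 3D path. Chemical validity (valences) is
# deliberately not enforced: the model consumes graphs, and unconstrained
# graphs keep the ground truth exact.

COMPOSITION_WEIGHTS <- c(C = 1, N = 2, O = 3, S = 4)
COMPOSITION_DEFAULT <- 0.5
BONDTYPE_WEIGHTS <- c(SINGLE = 1, DOUBLE = 3, TRIPLE = 5, AROMATIC = 2)

#' Synthetic dataset specification
#'
#' @param n_molecules Number of molecules.
#' @param atoms_range Inclusive range of atom counts per molecule.
#' @param elements Element pool.
#' @param element_probs Sampling probabilities over the pool (sum to 1).
#' @param bond_probs Named probabilities over `SINGLE`, `DOUBLE`, `TRIPLE`,
#'   `AROMATIC` (sum to 1).
#' @param ring_prob Probability of closing one extra ring edge on top of
#'   the random spanning tree.
#' @param mode Ground-truth mode: `"composition"` (sum of per-element
#'   weights: C=1, N=2, O=3, S=4, others 0.5), `"bondtype"`
#'   (1 per single + 3 per double + 5 per triple + 2 per aromatic bond),
#'   `"geometry"` (mean pairwise Euclidean distance), or `"mixed"`
#'   (composition + bondtype).
#' @param noise_sd Gaussian noise added to the noiseless target.
#' @param seed Seed for [make_dataset()].
#' @return List of class `synth_spec`.
#' @export
synth_spec <- function(n_molecules = 100L, atoms_range = c(4L, 12L),
                       elements = c("C", "N", "O", "S"),
                       element_probs = c(0.5, 0.2, 0.2, 0.1),
                       bond_probs = c(SINGLE = 0.6, DOUBLE = 0.2,
                                      TRIPLE = 0.1, AROMATIC = 0.1),
                       ring_prob = 0.3,
                       mode = c("composition", "bondtype", "geometry",
                                "mixed"),
                       noise_sd = 0.1, seed = 1L) {
  stopifnot(length(elements) == length(element_probs),
            abs(sum(element_probs) - 1) < 1e-9,
            setequal(names(bond_probs), BOND_TYPES[-1]),
            abs(sum(bond_probs) - 1) < 1e-9,
            noise_sd >= 0, ring_prob >= 0, ring_prob <= 1,
            atoms_range[1] >= 1, atoms_range[2] >= atoms_range[1])
  structure(list(n_molecules = as.integer(n_molecules),
                 atoms_range = as.integer(atoms_range),
                 elements = elements, element_probs = element_probs,
                 bond_probs = bond_probs[BOND_TYPES[-1]],
                 ring_prob = ring_prob, mode = match.arg(mode),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synth_spec")
}

# Uniform random labelled tree on n nodes via a random Pruefer sequence,
# restricted to trees with maximum degree 4 (an atom's degree in a tree is
# its Pruefer count + 1; rejection keeps the draw uniform over the
# restricted set). Unbounded hubs would be chemically meaningless and fall
# outside the featurization's degree domain.
random_tree_edges <- function(n, max_degree = 4L) {
  if (n == 1) return(cbind(i = integer(), j = integer()))
  if (n == 2) return(cbind(i = 1L, j = 2L))
  repeat {
    prufer <- sample.int(n, n - 2L, replace = TRUE)
    if (max(tabulate(prufer, n)) <= max_degree - 1L) break
  }
  degree <- rep(1L, n)
  for (v in prufer) degree[v] <- degree[v] + 1L
  edges <- matrix(0L, n - 1L, 2L)
  for (k in seq_len(n - 2L)) {
    leaf <- which(degree == 1L)[1]
    edges[k, ] <- c(leaf, prufer[k])
    degree[leaf] <- degree[leaf] - 1L
    degree[prufer[k]] <- degree[prufer[k]] - 1L
  }
  edges[n - 1L, ] <- which(degree == 1L)
  colnames(edges) <- c("i", "j")
  edges
}

#' Draw one random molecular graph
#'
#' A uniform random spanning tree over the drawn atom count, optionally one
#' ring-closing edge, bond types and elements drawn from the spec, and 3D
#' coordinates drawn from a standard Gaussian then scaled so the mean
#' bonded distance is 1. Consumes the current RNG state (seed with
#' `set.seed()` or use [make_dataset()]).
#'
#' @param spec A [synth_spec()].
#' @param id Molecule label.
#' @return A connected [molecular_graph()].
#' @export
random_molecular_graph <- function(spec, id = "synth") {
  n <- sample(seq(spec$atoms_range[1], spec$atoms_range[2]), 1)
  elements <- sample(spec$elements, n, replace = TRUE,
                     prob = spec$element_probs)
  edges <- random_tree_edges(n)
  if (n >= 3 && stats::runif(1) < spec$ring_prob) {
    # close one ring between a non-adjacent low-degree pair, if any exists
    adj <- matrix(FALSE, n, n)
    adj[edges] <- TRUE
    adj <- adj | t(adj) | diag(n) > 0
    deg <- tabulate(c(edges), n)
    ok <- deg <= 3L
    cand <- which(!adj & outer(ok, ok, `&`), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    if (nrow(cand))
      edges <- rbind(edges, cand[sample.int(nrow(cand), 1), , drop = FALSE])
  }
  types <- sample(names(spec$bond_probs), nrow(edges), replace = TRUE,
                  prob = spec$bond_probs)
  bonds <- data.frame(i = edges[, 1], j = edges[, 2], type = types,
                      stringsAsFactors = FALSE)
  C <- matrix(stats::rnorm(3 * n), n, 3)
  if (nrow(bonds)) {
    d <- sqrt(rowSums((C[bonds$i, , drop = FALSE] -
                         C[bonds$j, , drop = FALSE])^2))
    C <- C / mean(d)
  }
  molecular_graph(elements, bonds, C, id = id)
}

#' Noiseless ground-truth property of a graph
#'
#' `composition`: sum over atoms of the per-element weights (C=1, N=2,
#' O=3, S=4, others 0.5). `bondtype`: 1 per single + 3 per double + 5 per
#' triple + 2 per aromatic bond. `geometry`: mean pairwise Euclidean
#' distance over all atom pairs. `mixed`: composition + bondtype.
#'
#' @param graph A [molecular_graph()].
#' @param mode Property mode.
#' @return Numeric scalar.
#' @export
noiseless_property <- function(graph, mode = c("composition", "bondtype",
                                               "geometry", "mixed")) {
  mode <- match.arg(mode)
  comp <- function() {
    w <- COMPOSITION_WEIGHTS[graph$elements]
    w[is.na(w)] <- COMPOSITION_DEFAULT
    sum(w)
  }
  bond <- function() {
    if (!nrow(graph$bonds)) return(0)
    sum(BONDTYPE_WEIGHTS[graph$bonds$type])
  }
  switch(mode,
    composition = comp(),
    bondtype = bond(),
    mixed = comp() + bond(),
    geometry = {
      if (is.null(graph$C))
        stop("geometry mode requires coordinates", call. = FALSE)
      if (graph$n_atoms == 1) return(0)
      mean(stats::dist(graph$C))
    })
}

#' Generate a synthetic dataset
#'
#' `spec$n_molecules` records drawn from `spec$seed`; each target is the
#' noiseless ground truth plus Gaussian noise of sd `spec$noise_sd`. Every
#' record keeps its `noiseless_target` alongside.
#'
#' @param spec A [synth_spec()].
#' @return List of records `list(graph=, target=, noiseless_target=)`.
#' @export
make_dataset <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  with_seed(spec$seed, {
    lapply(seq_len(spec$n_molecules), function(k) {
      g <- random_molecular_graph(spec, id = sprintf("synth_%04d", k))
      y0 <- noiseless_property(g, spec$mode)
      list(graph = g, target = y0 + stats::rnorm(1, 0, spec$noise_sd),
           noiseless_target = y0)
    })
  })
}

#' A matched pair of graphs differing only in bond types
#'
#' Draws one graph and returns it together with a copy whose bond types
#' were resampled to differ somewhere (topology, elements and coordinates
#' identical). Types are restricted to `SINGLE`/`DOUBLE`/`TRIPLE` so the
#' atom-level features (which carry an aromaticity flag) are identical
#' too: a model seeing only unlabeled connectivity (the node path) cannot
#' distinguish the two, while the edge path can — the pair witnesses the
#' discriminative design of the bondtype task.
#'
#' @param spec A [synth_spec()].
#' @param seed Seed.
#' @return List of two [molecular_graph()] objects, `a` and `b`.
#' @export
matched_bondtype_pair <- function(spec, seed = 1L) {
  pr <- spec$bond_probs
  pr["AROMATIC"] <- 0
  pr <- pr / sum(pr)
  with_seed(seed, {
    repeat {
      a <- random_molecular_graph(spec, id = "pair_a")
      if (nrow(a$bonds) > 0) break
    }
    types_a <- sample(names(pr), nrow(a$bonds), replace = TRUE, prob = pr)
    bonds_a <- a$bonds
    bonds_a$type <- types_a
    a <- molecular_graph(a$elements, bonds_a, a$C, num_h = a$num_h,
                         charge = a$charge, id = "pair_a")
    repeat {
      types_b <- sample(names(pr), nrow(a$bonds), replace = TRUE, prob = pr)
      if (!identical(types_b, types_a)) break
    }
    bonds_b <- a$bonds
    bonds_b$type <- types_b
    b <- molecular_graph(a$elements, bonds_b, a$C, num_h = a$num_h,
                         charge = a$charge, id = "pair_b")
    list(a = a, b = b)
  })
}
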