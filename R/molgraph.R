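#' Bond type channels
#'
#' The model distinguishes five bond channels: the implicit bond of every
#' atom to itself plus the four chemical bond orders. Channel order is fixed
#' (`SELF` first) and shared by the adjacency stack, the edge-parameter
#' weights, and the fixed categorical edge values.
#'
#' @format Character vector of the five channel names in channel order.
#' @export
BOND_TYPES <- c("SELF", "SINGLE", "DOUBLE", "TRIPLE", "AROMATIC")

#' Supported element symbols
#'
#' The 42 elements recognised by the default featurization: the twelve
#' organic-chemistry staples first, then thirty further common elements in
#' atomic-number order. The position of a symbol in this vector is its
#' one-hot index in the first feature block. The list is frozen: changing it
#' changes the meaning of every stored feature matrix and checkpoint.
#'
#' @format Character vector of 42 element symbols.
#' @export
ELEMENTS <- c(
  "H", "B", "C", "N", "O", "F", "Si", "P", "S", "Cl", "Br", "I",
  "Li", "Be", "Na", "Mg", "Al", "K", "Ca", "Ti", "V", "Cr", "Mn", "Fe",
  "Co", "Ni", "Cu", "Zn", "Ga", "Ge", "As", "Se", "Zr", "Mo", "Ru", "Rh",
  "Pd", "Ag", "Cd", "Sn", "Sb", "Te"
)

# Feature layout: block offsets into the 60-dim initial atom feature.
# element(42) | degree(6: 0..5) | numH(5: 0..4) | charge(5: -2..+2) |
# aromatic(1) | in_ring(1)
FEATURE_DIM <- 60L
FEATURE_LAYOUT <- "element42-degree6-numh5-charge5-aromatic1-inring1"

#' Build the 60-dimensional initial feature vector of one atom
#'
#' Concatenates fixed-width one-hot blocks: element (42), heavy-atom degree
#' (6, for degrees 0..5), implicit/explicit hydrogen count (5, 0..4),
#' formal charge (5, -2..+2), plus aromaticity and ring-membership flags.
#'
#' @param element Element symbol; must be one of [ELEMENTS].
#' @param degree Number of bonded heavy-atom neighbours, 0..5.
#' @param num_h Number of attached hydrogens, 0..4.
#' @param charge Formal charge, -2..+2.
#' @param aromatic,in_ring Logical flags.
#' @return Numeric 0/1 vector of length 60 with 4, 5 or 6 ones.
#' @examples
#' f <- featurize_atom("C", degree = 4)
#' sum(f)  # 4: element, degree, numH and charge one-hots; both flags off
#' @export
featurize_atom <- function(element, degree = 0L, num_h = 0L, charge = 0L,
                           aromatic = FALSE, in_ring = FALSE) {
  idx <- match(element, ELEMENTS)
  if (is.na(idx))
    stop(sprintf("unsupported element symbol '%s'", element), call. = FALSE)
  if (degree < 0 || degree > 5) stop("degree must be in 0..5", call. = FALSE)
  if (num_h < 0 || num_h > 4) stop("num_h must be in 0..4", call. = FALSE)
  if (charge < -2 || charge > 2) stop("charge must be in -2..+2", call. = FALSE)
  v <- numeric(FEATURE_DIM)
  v[idx] <- 1
  v[42L + degree + 1L] <- 1
  v[48L + num_h + 1L] <- 1
  v[53L + charge + 3L] <- 1
  if (isTRUE(aromatic)) v[59L] <- 1
  if (isTRUE(in_ring)) v[60L] <- 1
  v
}

normalize_bonds <- function(bonds, n_atoms) {
  if (is.null(bonds) || NROW(bonds) == 0)
    return(data.frame(i = integer(), j = integer(), type = character(),
                      stringsAsFactors = FALSE))
  bonds <- as.data.frame(bonds)
  stopifnot(all(c("i", "j", "type") %in% names(bonds)))
  bonds$i <- as.integer(bonds$i)
  bonds$j <- as.integer(bonds$j)
  bonds$type <- as.character(bonds$type)
  if (any(bonds$i == bonds$j))
    stop("self bonds (i == j) are implicit and must not be listed", call. = FALSE)
  if (any(bonds$i < 1 | bonds$i > n_atoms | bonds$j < 1 | bonds$j > n_atoms))
    stop("bond indices out of range 1..n_atoms", call. = FALSE)
  bad <- setdiff(unique(bonds$type), BOND_TYPES[-1])
  if (length(bad))
    stop(sprintf("unknown bond type(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  # canonical orientation i < j, drop exact duplicates, detect conflicts
  lo <- pmin(bonds$i, bonds$j); hi <- pmax(bonds$i, bonds$j)
  bonds$i <- lo; bonds$j <- hi
  bonds <- unique(bonds[, c("i", "j", "type")])
  key <- paste(bonds$i, bonds$j)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop(sprintf("conflicting bond types for atom pair (%s)", dup),
         call. = FALSE)
  }
  bonds[order(bonds$i, bonds$j), , drop = FALSE]
}

#' Build the five-channel adjacency stack
#'
#' Returns a binary `[5 x N x N]` array, one `N x N` adjacency matrix per
#' bond channel. The `SELF` channel is the identity; each real bond sets a
#' symmetric pair of entries in exactly one of the other four channels.
#'
#' @param bonds `data.frame` with columns `i`, `j` (1-based atom indices,
#'   `i != j`) and `type` (one of `SINGLE`, `DOUBLE`, `TRIPLE`, `AROMATIC`);
#'   or `NULL` for no bonds.
#' @param n_atoms Number of atoms N.
#' @return Numeric array `[5 x N x N]` with `dimnames` on the first margin.
#' @export
build_adjacency <- function(bonds, n_atoms) {
  n_atoms <- as.integer(n_atoms)
  stopifnot(n_atoms >= 1)
  bonds <- normalize_bonds(bonds, n_atoms)
  A <- array(0, c(5L, n_atoms, n_atoms),
             dimnames = list(BOND_TYPES, NULL, NULL))
  A[1L, , ] <- diag(n_atoms)
  if (nrow(bonds)) {
    ch <- match(bonds$type, BOND_TYPES)
    for (r in seq_len(nrow(bonds))) {
      A[ch[r], bonds$i[r], bonds$j[r]] <- 1
      A[ch[r], bonds$j[r], bonds$i[r]] <- 1
    }
  }
  A
}

#' Recover the bond list from an adjacency stack
#'
#' Inverse of [build_adjacency()]: reads the four non-self channels back
#' into a canonical `(i, j, type)` bond table with `i < j`.
#'
#' @param A Adjacency stack `[5 x N x N]`.
#' @return `data.frame` with columns `i`, `j`, `type`.
#' @export
bonds_from_adjacency <- function(A) {
  stopifnot(length(dim(A)) == 3, dim(A)[1] == 5)
  n <- dim(A)[2]
  out <- list()
  for (ch in 2:5) {
    M <- A[ch, , ]
    idx <- which(upper.tri(matrix(0, n, n)) & M == 1, arr.ind = TRUE)
    if (nrow(idx))
      out[[length(out) + 1L]] <- data.frame(
        i = idx[, 1], j = idx[, 2], type = BOND_TYPES[ch],
        stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(i = integer(), j = integer(), type = character(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$i, res$j), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Atoms lying on a cycle: those with at least one incident non-bridge edge.
ring_atoms <- function(bonds, n_atoms) {
  inring <- rep(FALSE, n_atoms)
  if (NROW(bonds) < 3) return(inring)
  g <- igraph::graph_from_edgelist(cbind(bonds$i, bonds$j), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n_atoms - igraph::vcount(g)))
  br <- igraph::bridges(g)
  keep <- igraph::delete_edges(g, br)
  deg <- igraph::degree(keep)
  inring[seq_along(deg)] <- deg > 0
  inring
}

# Static per-graph tensors used by every path layer: the ordered pair list
# (i, j) with j in N(i) (self included), the bond channel of each pair, and
# the summed relative-coordinate weight of each pair.
graph_pair_cache <- function(n_atoms, bonds, C) {
  nbr <- vector("list", n_atoms)
  for (i in seq_len(n_atoms)) nbr[[i]] <- i
  chan_of <- vector("list", n_atoms)
  for (i in seq_len(n_atoms)) chan_of[[i]] <- 1L
  if (NROW(bonds)) {
    ch <- match(bonds$type, BOND_TYPES)
    for (r in seq_len(nrow(bonds))) {
      i <- bonds$i[r]; j <- bonds$j[r]
      nbr[[i]] <- c(nbr[[i]], j); chan_of[[i]] <- c(chan_of[[i]], ch[r])
      nbr[[j]] <- c(nbr[[j]], i); chan_of[[j]] <- c(chan_of[[j]], ch[r])
    }
  }
  pi_ <- rep.int(seq_len(n_atoms), lengths(nbr))
  pj_ <- unlist(nbr, use.names = FALSE)
  chan <- unlist(chan_of, use.names = FALSE)
  s <- NULL
  if (!is.null(C)) {
    d <- C[pi_, , drop = FALSE] - C[pj_, , drop = FALSE]
    s <- rowSums(d)
  }
  list(n = n_atoms, K = length(pi_), pi = pi_, pj = pj_, chan = chan, s = s)
}

#' Construct a molecular graph
#'
#' The central data container: atoms with element symbols, typed bonds held
#' as a five-channel adjacency stack, optional 3D coordinates, and the
#' 60-dimensional initial atom features built with [featurize_atom()].
#' Atom indices are 1-based.
#'
#' @param elements Character vector of element symbols (heavy atoms).
#' @param bonds Bond table as for [build_adjacency()].
#' @param coords Optional `N x 3` numeric matrix of 3D coordinates.
#' @param num_h,charge Per-atom hydrogen counts and formal charges
#'   (recycled scalars allowed).
#' @param aromatic Optional logical vector; default: atoms with an incident
#'   `AROMATIC` bond.
#' @param in_ring Optional logical vector; default: atoms on a cycle of the
#'   bond graph.
#' @param id Molecule label.
#' @return An object of class `molecular_graph`.
#' @examples
#' g <- molecular_graph(c("C", "C"), data.frame(i = 1, j = 2, type = "SINGLE"))
#' g$A["SINGLE", , ]
#' @export
molecular_graph <- function(elements, bonds = NULL, coords = NULL,
                            num_h = 0L, charge = 0L, aromatic = NULL,
                            in_ring = NULL, id = "mol") {
  n <- length(elements)
  stopifnot(n >= 1)
  bonds <- normalize_bonds(bonds, n)
  A <- build_adjacency(bonds, n)
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    if (!is.numeric(coords) || nrow(coords) != n || ncol(coords) != 3)
      stop_shape("coords", c(n, 3), dim(coords))
    if (!all(is.finite(coords))) stop("coords must be finite", call. = FALSE)
  }
  num_h <- rep_len(as.integer(num_h), n)
  charge <- rep_len(as.integer(charge), n)
  deg <- tabulate(c(bonds$i, bonds$j), nbins = n)
  if (is.null(aromatic)) {
    aromatic <- rep(FALSE, n)
    ar <- bonds[bonds$type == "AROMATIC", ]
    aromatic[unique(c(ar$i, ar$j))] <- TRUE
  }
  if (is.null(in_ring)) in_ring <- ring_atoms(bonds, n)
  H <- matrix(0, n, FEATURE_DIM)
  for (k in seq_len(n))
    H[k, ] <- featurize_atom(elements[k], deg[k], num_h[k], charge[k],
                             aromatic[k], in_ring[k])
  structure(list(
    n_atoms = n, elements = elements, bonds = bonds, A = A, C = coords,
    H_init = H, num_h = num_h, charge = charge, aromatic = aromatic,
    in_ring = in_ring, id = as.character(id),
    cache = graph_pair_cache(n, bonds, coords)
  ), class = "molecular_graph")
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat(sprintf("<molecular_graph '%s': %d atoms, %d bonds%s>\n",
              x$id, x$n_atoms, nrow(x$bonds),
              if (is.null(x$C)) "" else ", 3D"))
  if (nrow(x$bonds)) {
    tab <- table(factor(x$bonds$type, levels = BOND_TYPES[-1]))
    cat("  bonds:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "),
        "\n")
  }
  cat("  elements:", paste(x$elements, collapse = " "), "\n")
  invisible(x)
}
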