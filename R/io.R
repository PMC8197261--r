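# SMILES and SDF input, plus the dataset writers used by the synthetic
# generator. SMILES are parsed through the OpenBabel executable (MOL2
# output carries aromatic bond perception, explicit hydrogens and formal
# charges); SDF V2000 is read with ChemmineR.

obabel_path <- function() {
  p <- Sys.which("obabel")
  if (!nzchar(p))
    stop("the 'obabel' executable (OpenBabel) is required for SMILES input ",
         "but was not found on PATH", call. = FALSE)
  p
}

# Convert a vector of SMILES to MOL2 text via obabel, explicit hydrogens
# added. Molecule titles carry the input index so unparseable inputs can be
# mapped back to their rows. Returns the raw MOL2 lines.
smiles_to_mol2 <- function(smiles, embed_3d = FALSE, gen2d = FALSE) {
  smi <- tempfile(fileext = ".smi")
  out <- tempfile(fileext = ".mol2")
  on.exit(unlink(c(smi, out)))
  writeLines(paste(smiles, seq_along(smiles)), smi)
  args <- c(smi, "-omol2", "-O", out, "-h", "-e")
  if (embed_3d) args <- c(args, if (gen2d) "--gen2d" else "--gen3d")
  suppressWarnings(system2(obabel_path(), args, stdout = FALSE, stderr = FALSE))
  if (!file.exists(out)) return(character())
  readLines(out, warn = FALSE)
}

# Formal charges from the UNITY_ATOM_ATTR sections of MOL2 text, per
# molecule record: list of named numeric vectors (atom index -> charge).
mol2_formal_charges <- function(lines) {
  recs <- split(lines, cumsum(grepl("^@<TRIPOS>MOLECULE", lines)))
  recs <- recs[names(recs) != "0"]
  lapply(recs, function(rl) {
    out <- numeric()
    k <- which(grepl("^@<TRIPOS>UNITY_ATOM_ATTR", rl))
    if (!length(k)) return(out)
    r <- k[1] + 1L
    while (r <= length(rl) && !grepl("^@<TRIPOS>", rl[r])) {
      hdr <- scan(text = rl[r], quiet = TRUE)
      atom <- hdr[1]; nattr <- hdr[2]; r <- r + 1L
      for (a in seq_len(nattr)) {
        f <- strsplit(trimws(rl[r]), "\\s+")[[1]]
        if (f[1] == "charge") out[as.character(atom)] <- as.numeric(f[2])
        r <- r + 1L
      }
    }
    out
  })
}

mol2_bond_type <- function(ty) {
  map <- c("1" = "SINGLE", "2" = "DOUBLE", "3" = "TRIPLE",
           "ar" = "AROMATIC", "am" = "SINGLE")
  out <- unname(map[ty])
  if (anyNA(out)) {
    warning(sprintf("unrecognised MOL2 bond type(s) %s treated as SINGLE",
                    paste(unique(ty[is.na(out)]), collapse = ", ")))
    out[is.na(out)] <- "SINGLE"
  }
  out
}

# One bio3d mol2 record (explicit H) -> molecular_graph on heavy atoms.
mol2_to_graph <- function(m, fcharge, id, keep_coords) {
  at <- m$atom
  el <- sub("\\..*$", "", at$elety)
  el[el == "Du"] <- at$elena[el == "Du"]
  heavy <- which(el != "H")
  if (!length(heavy)) heavy <- seq_len(nrow(at))  # e.g. molecular hydrogen
  idx_map <- integer(nrow(at)); idx_map[heavy] <- seq_along(heavy)
  bd <- m$bond
  num_h <- integer(length(heavy))
  keep <- logical(NROW(bd))
  if (NROW(bd)) {
    for (r in seq_len(nrow(bd))) {
      o <- bd$origin[r]; t <- bd$target[r]
      oh <- el[o] == "H"; th <- el[t] == "H"
      if (oh && !th && idx_map[t] > 0) num_h[idx_map[t]] <- num_h[idx_map[t]] + 1L
      if (th && !oh && idx_map[o] > 0) num_h[idx_map[o]] <- num_h[idx_map[o]] + 1L
      keep[r] <- !oh && !th
    }
  }
  bonds <- NULL
  if (any(keep)) {
    bd <- bd[keep, , drop = FALSE]
    bonds <- data.frame(i = idx_map[bd$origin], j = idx_map[bd$target],
                        type = mol2_bond_type(as.character(bd$type)),
                        stringsAsFactors = FALSE)
  }
  charge <- integer(length(heavy))
  if (length(fcharge)) {
    ai <- as.integer(names(fcharge))
    for (k in seq_along(ai))
      if (idx_map[ai[k]] > 0) charge[idx_map[ai[k]]] <- as.integer(fcharge[k])
  }
  coords <- NULL
  if (keep_coords)
    coords <- as.matrix(at[heavy, c("x", "y", "z")])
  aromatic <- grepl("\\.ar$", at$elety[heavy])
  g <- molecular_graph(el[heavy], bonds, coords, num_h = num_h,
                       charge = pmin(2L, pmax(-2L, charge)), id = id)
  # keep OpenBabel's aromatic atom perception when it adds to bond-derived flags
  if (any(aromatic & !g$aromatic)) {
    g <- molecular_graph(el[heavy], bonds, coords, num_h = num_h,
                         charge = pmin(2L, pmax(-2L, charge)),
                         aromatic = aromatic | g$aromatic, id = id)
  }
  g
}

parse_mol2_records <- function(lines, keep_coords) {
  tf <- tempfile(fileext = ".mol2")
  on.exit(unlink(tf))
  writeLines(lines, tf)
  mols <- bio3d::read.mol2(tf)
  if (inherits(mols, "mol2")) mols <- list(mols)
  fch <- mol2_formal_charges(lines)
  graphs <- vector("list", length(mols))
  ids <- character(length(mols))
  for (k in seq_along(mols)) {
    ids[k] <- mols[[k]]$name
    graphs[[k]] <- mol2_to_graph(mols[[k]], if (k <= length(fch)) fch[[k]] else numeric(),
                                 id = ids[k], keep_coords = keep_coords)
  }
  names(graphs) <- ids
  graphs
}

#' Parse a SMILES string into a molecular graph
#'
#' Uses OpenBabel for structure perception. Hydrogens are implicit (heavy
#' atom graph with per-atom H counts); aromatic ring bonds map to the
#' `AROMATIC` channel rather than alternating single/double. With
#' `embed_3d = TRUE` a single 3D conformer is generated deterministically;
#' molecules that fail to embed fall back to a flat 2D layout at z = 0,
#' with a warning.
#'
#' @param smiles A single SMILES string.
#' @param embed_3d Generate 3D coordinates?
#' @return A [molecular_graph()].
#' @examples
#' \dontrun{
#' benzene <- mol_from_smiles("c1ccccc1")
#' table(benzene$bonds$type)
#' }
#' @export
mol_from_smiles <- function(smiles, embed_3d = FALSE) {
  stopifnot(is.character(smiles), length(smiles) == 1)
  lines <- smiles_to_mol2(smiles, embed_3d = embed_3d)
  if (!length(lines))
    stop(sprintf("SMILES could not be parsed: '%s'", smiles), call. = FALSE)
  g <- parse_mol2_records(lines, keep_coords = embed_3d)[[1]]
  if (embed_3d && g$n_atoms > 1 && all(abs(g$C) < 1e-8)) {
    lines <- smiles_to_mol2(smiles, embed_3d = TRUE, gen2d = TRUE)
    g <- parse_mol2_records(lines, keep_coords = TRUE)[[1]]
    warning(sprintf("3D embedding failed for '%s'; using 2D layout at z = 0",
                    smiles))
  }
  g$id <- smiles
  g
}

#' Read a SMILES/target CSV dataset
#'
#' One record per parseable row; rows whose SMILES OpenBabel cannot parse
#' are skipped with a warning and counted in the `n_skipped` attribute.
#'
#' @param path CSV file with a header row.
#' @param smiles_col,target_col Column names.
#' @param embed_3d Generate 3D coordinates for each molecule?
#' @return List of records `list(graph = <molecular_graph>, target = <num>)`,
#'   with attribute `n_skipped`.
#' @export
read_csv_dataset <- function(path, smiles_col = "smiles",
                             target_col = "target", embed_3d = FALSE) {
  stopifnot(file.exists(path))
  if (file.size(path) == 0)
    return(structure(list(), n_skipped = 0L))
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  for (col in c(smiles_col, target_col))
    if (!col %in% names(df))
      stop(sprintf("column '%s' not found; available: %s", col,
                   paste(names(df), collapse = ", ")), call. = FALSE)
  if (nrow(df) == 0)
    return(structure(list(), n_skipped = 0L))
  smiles <- as.character(df[[smiles_col]])
  targets <- as.numeric(df[[target_col]])
  lines <- smiles_to_mol2(smiles, embed_3d = embed_3d)
  graphs <- if (length(lines)) parse_mol2_records(lines, keep_coords = embed_3d)
            else list()
  got <- as.integer(names(graphs))
  skipped <- setdiff(seq_along(smiles), got)
  if (length(skipped))
    warning(sprintf("skipped %d unparseable SMILES row(s): %s",
                    length(skipped),
                    paste(utils::head(skipped, 5), collapse = ", ")))
  records <- vector("list", length(got))
  for (k in seq_along(got)) {
    g <- graphs[[k]]
    g$id <- smiles[got[k]]
    records[[k]] <- list(graph = g, target = targets[got[k]])
  }
  structure(records, n_skipped = length(skipped))
}

sdf_mchg_charges <- function(rec_lines) {
  out <- numeric()
  for (ln in grep("^M  CHG", rec_lines, value = TRUE)) {
    f <- scan(text = sub("^M  CHG", "", ln), quiet = TRUE)
    n <- f[1]
    for (k in seq_len(n))
      out[as.character(f[2 * k])] <- f[2 * k + 1]
  }
  out
}

#' Read an SDF (V2000) dataset with a named property field
#'
#' Coordinates are taken verbatim from the atom block (no re-embedding).
#' Explicit hydrogens are collapsed into per-atom H counts; bond type 4 in
#' the bond block maps to the `AROMATIC` channel. Records missing the
#' property field are skipped with a warning.
#'
#' @param path SDF file.
#' @param property_field Name of the data field holding the numeric target.
#' @return List of records as in [read_csv_dataset()].
#' @export
read_sdf_dataset <- function(path, property_field = "target") {
  stopifnot(file.exists(path))
  if (file.size(path) == 0)
    return(structure(list(), n_skipped = 0L))
  sdfs <- suppressWarnings(ChemmineR::read.SDFset(path))
  raw <- readLines(path, warn = FALSE)
  rec_id <- cumsum(c(1, utils::head(grepl("^\\$\\$\\$\\$", raw), -1)))
  rec_text <- split(raw, rec_id)
  records <- list()
  skipped <- 0L
  for (k in seq_along(sdfs)) {
    sdf <- sdfs[[k]]
    props <- ChemmineR::datablock(sdf)
    if (!property_field %in% names(props)) {
      warning(sprintf("SDF record %d missing field '%s'; skipped",
                      k, property_field))
      skipped <- skipped + 1L
      next
    }
    ab <- ChemmineR::atomblock(sdf)
    el <- sub("_.*$", "", rownames(ab))
    coords <- unname(as.matrix(ab[, 1:3, drop = FALSE]))
    bb <- ChemmineR::bondblock(sdf)
    bonds <- NULL
    if (NROW(bb)) {
      ty <- c("1" = "SINGLE", "2" = "DOUBLE", "3" = "TRIPLE",
              "4" = "AROMATIC")[as.character(bb[, 3])]
      bonds <- data.frame(i = as.integer(bb[, 1]), j = as.integer(bb[, 2]),
                          type = unname(ty), stringsAsFactors = FALSE)
    }
    chg <- if (k <= length(rec_text)) sdf_mchg_charges(rec_text[[k]]) else numeric()
    # collapse explicit hydrogens
    hv <- which(el != "H")
    if (length(hv) == 0) hv <- seq_along(el)
    idx_map <- integer(length(el)); idx_map[hv] <- seq_along(hv)
    num_h <- integer(length(hv))
    if (!is.null(bonds)) {
      keep <- logical(nrow(bonds))
      for (r in seq_len(nrow(bonds))) {
        i <- bonds$i[r]; j <- bonds$j[r]
        ih <- el[i] == "H"; jh <- el[j] == "H"
        if (ih && !jh) num_h[idx_map[j]] <- num_h[idx_map[j]] + 1L
        if (jh && !ih) num_h[idx_map[i]] <- num_h[idx_map[i]] + 1L
        keep[r] <- !ih && !jh
      }
      bonds <- bonds[keep, , drop = FALSE]
      bonds$i <- idx_map[bonds$i]; bonds$j <- idx_map[bonds$j]
      if (!nrow(bonds)) bonds <- NULL
    }
    charge <- integer(length(hv))
    if (length(chg)) {
      ai <- as.integer(names(chg))
      for (q in seq_along(ai))
        if (idx_map[ai[q]] > 0) charge[idx_map[ai[q]]] <- as.integer(chg[q])
    }
    g <- molecular_graph(el[hv], bonds, coords[hv, , drop = FALSE],
                         num_h = num_h,
                         charge = pmin(2L, pmax(-2L, charge)),
                         id = ChemmineR::sdfid(sdf))
    records[[length(records) + 1L]] <-
      list(graph = g, target = as.numeric(props[[property_field]]))
  }
  structure(records, n_skipped = skipped)
}

#' Write records to an SDF (V2000) file
#'
#' The dialect written is exactly what [read_sdf_dataset()] reads back:
#' aromatic bonds as bond type 4, the target in a named data field, formal
#' charges as `M  CHG` lines. Graphs without coordinates are written at the
#' origin.
#'
#' @param records List of `list(graph=, target=)` records.
#' @param path Output file.
#' @param property_field Data field name for the target.
#' @export
write_sdf_dataset <- function(records, path, property_field = "target") {
  con <- file(path, "w")
  on.exit(close(con))
  for (rec in records) {
    g <- rec$graph
    C <- g$C
    if (is.null(C)) C <- matrix(0, g$n_atoms, 3)
    lines <- c(g$id, "  mpgcn", "",
               sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                       g$n_atoms, nrow(g$bonds)))
    for (i in seq_len(g$n_atoms))
      lines <- c(lines, sprintf(
        "%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
        C[i, 1], C[i, 2], C[i, 3], g$elements[i]))
    if (nrow(g$bonds)) {
      ty <- match(g$bonds$type, BOND_TYPES) - 1L  # SINGLE=1 .. AROMATIC=4
      lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0",
                                g$bonds$i, g$bonds$j, ty))
    }
    chg <- which(g$charge != 0)
    while (length(chg)) {
      take <- utils::head(chg, 8)
      chg <- chg[-seq_along(take)]
      lines <- c(lines, paste0(
        sprintf("M  CHG%3d", length(take)),
        paste0(sprintf("%4d%4d", take, g$charge[take]), collapse = "")))
    }
    lines <- c(lines, "M  END",
               sprintf("> <%s>", property_field),
               format(rec$target, digits = 17), "", "$$$$")
    writeLines(lines, con)
  }
  invisible(path)
}

# Minimal SMILES writer for arbitrary molecular graphs (DFS spanning tree
# with numbered ring closures; bracket atoms carrying explicit H counts).
# Aromatic channels are emitted as ':' bonds on lowercase atoms; graphs
# whose aromatic systems are not chemically aromatic may not survive a
# round trip through an external parser -- the SDF writer is the lossless
# dialect.
graph_to_smiles <- function(graph) {
  n <- graph$n_atoms
  bsym <- c(SINGLE = "-", DOUBLE = "=", TRIPLE = "#", AROMATIC = ":")
  nbr <- vector("list", n)
  btyp <- vector("list", n)
  if (nrow(graph$bonds))
    for (r in seq_len(nrow(graph$bonds))) {
      i <- graph$bonds$i[r]; j <- graph$bonds$j[r]; t <- graph$bonds$type[r]
      nbr[[i]] <- c(nbr[[i]], j); btyp[[i]] <- c(btyp[[i]], t)
      nbr[[j]] <- c(nbr[[j]], i); btyp[[j]] <- c(btyp[[j]], t)
    }
  # pass 1: classify edges into traversal-tree edges and ring-closure edges
  seen <- rep(FALSE, n)
  tree <- new.env(); done <- new.env(); closure <- vector("list", n)
  ring_no <- 0L
  roots <- integer()
  for (s in seq_len(n)) {
    if (seen[s]) next
    roots <- c(roots, s)
    stack <- s
    seen[s] <- TRUE
    while (length(stack)) {
      i <- stack[[length(stack)]]; stack <- stack[-length(stack)]
      for (k in seq_along(nbr[[i]])) {
        j <- nbr[[i]][k]
        key <- paste0(min(i, j), "_", max(i, j))
        if (!seen[j]) {
          seen[j] <- TRUE
          assign(key, TRUE, envir = tree)
          assign(key, TRUE, envir = done)
          stack <- c(stack, j)
        } else if (!exists(key, envir = done)) {
          assign(key, TRUE, envir = done)
          ring_no <- ring_no + 1L
          d <- if (ring_no < 10) as.character(ring_no)
               else sprintf("%%%02d", ring_no)
          tok <- paste0(bsym[[btyp[[i]][k]]], d)
          closure[[i]] <- c(closure[[i]], tok)
          closure[[j]] <- c(closure[[j]], tok)
        }
      }
    }
  }
  atom_tok <- function(i) {
    el <- graph$elements[i]
    sym <- if (graph$aromatic[i] && nchar(el) == 1) tolower(el) else el
    h <- graph$num_h[i]
    q <- graph$charge[i]
    qs <- if (q > 0) paste0("+", if (q > 1) q else "")
          else if (q < 0) paste0("-", if (q < -1) -q else "") else ""
    paste0("[", sym, if (h == 1) "H" else if (h > 1) paste0("H", h) else "",
           qs, "]", paste0(closure[[i]], collapse = ""))
  }
  # pass 2: emit along the same DFS tree
  visited <- rep(FALSE, n)
  emit <- function(i, from) {
    visited[i] <<- TRUE
    out <- atom_tok(i)
    kids <- character()
    for (k in seq_along(nbr[[i]])) {
      j <- nbr[[i]][k]
      if (visited[j]) next
      key <- paste0(min(i, j), "_", max(i, j))
      if (!exists(key, envir = tree)) next
      kids <- c(kids, paste0(bsym[[btyp[[i]][k]]], emit(j, i)))
    }
    if (length(kids)) {
      out <- paste0(out,
                    paste0(sprintf("(%s)", utils::head(kids, -1)),
                           collapse = ""),
                    utils::tail(kids, 1))
    }
    out
  }
  paste(vapply(roots, function(s) emit(s, 0L), ""), collapse = ".")
}

#' Write records to a SMILES/target CSV
#'
#' SMILES are produced by a structural serializer; for synthetic graphs
#' whose bond patterns are not chemically valid the SMILES may not be
#' re-perceived identically by external software. Use [write_sdf_dataset()]
#' for a lossless round trip.
#'
#' @inheritParams write_sdf_dataset
#' @param smiles_col,target_col Column names to write.
#' @export
write_csv_dataset <- function(records, path, smiles_col = "smiles",
                              target_col = "target") {
  df <- data.frame(
    smiles = vapply(records, function(r) graph_to_smiles(r$graph), ""),
    target = vapply(records, function(r) r$target, 0)
  )
  names(df) <- c(smiles_col, target_col)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Dump featurized graphs as a compressed table with a layout sidecar
#'
#' Writes `features.csv.gz` (one row per atom: molecule id, atom index, the
#' 60 feature columns) and `layout.json` describing the one-hot block
#' layout, into `dir`.
#'
#' @param records List of records.
#' @param dir Output directory (created if needed).
#' @export
write_features <- function(records, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(records, function(r) {
    g <- r$graph
    data.frame(mol_id = g$id, atom_idx = seq_len(g$n_atoms), g$H_init)
  })
  df <- do.call(rbind, rows)
  names(df) <- c("mol_id", "atom_idx", sprintf("f%02d", seq_len(FEATURE_DIM)))
  con <- gzfile(file.path(dir, "features.csv.gz"), "w")
  utils::write.csv(df, con, row.names = FALSE)
  close(con)
  jsonlite::write_json(list(
    layout = FEATURE_LAYOUT,
    blocks = list(element = ELEMENTS, degree = 0:5, num_h = 0:4,
                  charge = -2:2, flags = c("aromatic", "in_ring")),
    feature_dim = FEATURE_DIM
  ), file.path(dir, "layout.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
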