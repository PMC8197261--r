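test_that("atom featurization follows the fixed one-hot block layout", {
  f <- featurize_atom("C", degree = 4, num_h = 0, charge = 0,
                      aromatic = FALSE, in_ring = FALSE)
  expect_length(f, 60)
  expect_setequal(which(f == 1),
                  c(match("C", ELEMENTS), 42 + 4 + 1, 48 + 0 + 1, 53 + 0 + 3))
  expect_equal(sum(featurize_atom("O", degree = 2)), 4)
  expect_equal(sum(featurize_atom("C", degree = 2, num_h = 1,
                                  aromatic = TRUE, in_ring = TRUE)), 6)
  # one one-hot per block, plus set flags, never more than 6
  for (el in c("H", "S", "Br", "Te")) {
    f <- featurize_atom(el, degree = 3, num_h = 2, charge = -1,
                        aromatic = TRUE, in_ring = FALSE)
    expect_equal(sum(f), 5)
    expect_true(all(f %in% c(0, 1)))
  }
})

test_that("unsupported elements and out-of-range values are rejected by name", {
  expect_error(featurize_atom("Xx"), "Xx")
  expect_error(featurize_atom("C", degree = 6), "degree")
  expect_error(featurize_atom("C", num_h = 5), "num_h")
  expect_error(featurize_atom("C", charge = 3), "charge")
})

test_that("adjacency stack has identity SELF channel and symmetric bond channels", {
  A <- build_adjacency(data.frame(i = 1, j = 2, type = "SINGLE"), 2)
  expect_equal(A["SINGLE", , ], matrix(c(0, 1, 1, 0), 2))
  expect_equal(A["SELF", , ], diag(2))
  expect_equal(sum(A[c("DOUBLE", "TRIPLE", "AROMATIC"), , ]), 0)

  A1 <- build_adjacency(NULL, 1)
  expect_equal(unname(A1["SELF", , , drop = TRUE]), 1)
  expect_equal(sum(A1), 1)

  # benzene: N + 2 * |bonds| entries
  ring <- data.frame(i = 1:6, j = c(2:6, 1), type = "AROMATIC")
  expect_equal(sum(build_adjacency(ring, 6)), 6 + 12)
})

test_that("adjacency construction rejects malformed bonds", {
  expect_error(build_adjacency(data.frame(i = 1, j = 1, type = "SINGLE"), 2),
               "implicit")
  expect_error(build_adjacency(
    data.frame(i = c(1, 2), j = c(2, 1), type = c("SINGLE", "DOUBLE")), 2),
    "conflicting")
  expect_error(build_adjacency(data.frame(i = 1, j = 5, type = "SINGLE"), 2),
               "range")
})

test_that("bond list round-trips through the adjacency stack", {
  for (seed in 1:5) {
    g <- rand_graph(seed)
    back <- bonds_from_adjacency(g$A)
    expect_equal(back, g$bonds, ignore_attr = TRUE)
  }
})

test_that("molecular_graph invariants hold for generated graphs", {
  for (seed in 1:5) {
    g <- rand_graph(seed)
    expect_equal(g$A["SELF", , ], diag(g$n_atoms), ignore_attr = TRUE)
    for (ch in BOND_TYPES[-1]) {
      expect_equal(g$A[ch, , ], t(g$A[ch, , ]))
      expect_true(all(diag(g$A[ch, , ]) == 0))
    }
    # at most one non-SELF channel per pair
    expect_true(all(apply(g$A[-1, , , drop = FALSE], c(2, 3), sum) <= 1))
    expect_equal(ncol(g$H_init), 60)
    expect_true(all(g$H_init %in% c(0, 1)))
  }
})

has_obabel <- nzchar(Sys.which("obabel"))

test_that("SMILES parsing produces correct small-molecule graphs", {
  skip_if_not(has_obabel, "obabel not on PATH")
  w <- mol_from_smiles("O")
  expect_equal(w$n_atoms, 1)
  expect_equal(nrow(w$bonds), 0)
  expect_equal(w$num_h, 2L)

  e <- mol_from_smiles("CC")
  expect_equal(e$n_atoms, 2)
  expect_equal(e$bonds$type, "SINGLE")

  b <- mol_from_smiles("c1ccccc1")
  expect_equal(b$n_atoms, 6)
  expect_equal(sum(b$bonds$type == "AROMATIC"), 6)
  expect_true(all(b$aromatic))
  expect_true(all(b$in_ring))

  expect_error(mol_from_smiles("notasmiles[[["), "notasmiles")
})

test_that("CSV reader returns one record per parseable row and counts skips", {
  skip_if_not(has_obabel, "obabel not on PATH")
  tmp <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(smiles = c("CC", "O=C=O", "CCO"), target = 1:3),
            tmp, row.names = FALSE)
  recs <- read_csv_dataset(tmp)
  expect_length(recs, 3)
  expect_equal(attr(recs, "n_skipped"), 0)
  expect_equal(vapply(recs, `[[`, 0, "target"), c(1, 2, 3))

  write.csv(data.frame(smiles = c("CC", "???bad???", "CCO"), target = 1:3),
            tmp, row.names = FALSE)
  expect_warning(recs <- read_csv_dataset(tmp), "skipped 1")
  expect_length(recs, 2)
  expect_equal(attr(recs, "n_skipped"), 1)
  expect_equal(vapply(recs, `[[`, 0, "target"), c(1, 3))

  writeLines("smiles,target", tmp)
  expect_length(read_csv_dataset(tmp), 0)

  write.csv(data.frame(smiles = "CC", y = 1), tmp, row.names = FALSE)
  expect_error(read_csv_dataset(tmp), "available: smiles, y")
})

test_that("SDF reader echoes coordinates and skips records missing the field", {
  tmp <- withr::local_tempfile(fileext = ".sdf")
  writeLines(c(
    "mol1", "  test", "",
    "  2  1  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 C   0  0  0  0  0  0  0  0  0  0  0  0",
    "    1.5000    0.0000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
    "  1  2  1  0  0  0  0",
    "M  END",
    "> <target>", "3.25", "", "$$$$",
    "mol2", "  test", "",
    "  1  0  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 N   0  0  0  0  0  0  0  0  0  0  0  0",
    "M  END",
    "> <other>", "9", "", "$$$$"), tmp)
  expect_warning(recs <- read_sdf_dataset(tmp), "missing field")
  expect_length(recs, 1)
  expect_equal(recs[[1]]$graph$C[2, ], c(1.5, 0, 0))
  expect_equal(recs[[1]]$target, 3.25)
  expect_equal(attr(recs, "n_skipped"), 1)
})

test_that("synthetic datasets round-trip through the SDF dialect", {
  recs <- make_dataset(synth_spec(n_molecules = 6, mode = "bondtype",
                                  seed = 11))
  tmp <- withr::local_tempfile(fileext = ".sdf")
  write_sdf_dataset(recs, tmp)
  back <- read_sdf_dataset(tmp)
  expect_length(back, length(recs))
  expect_equal(vapply(back, `[[`, 0, "target"),
               vapply(recs, `[[`, 0, "target"))
  for (k in seq_along(recs)) {
    expect_equal(back[[k]]$graph$bonds, recs[[k]]$graph$bonds,
                 ignore_attr = TRUE)
    expect_equal(back[[k]]$graph$elements, recs[[k]]$graph$elements)
    expect_lt(max(abs(back[[k]]$graph$C - recs[[k]]$graph$C)), 1e-3)
  }
})

test_that("feature dump writes the table and layout sidecar", {
  recs <- make_dataset(synth_spec(n_molecules = 3, seed = 2))
  dir <- withr::local_tempdir()
  write_features(recs, dir)
  expect_true(file.exists(file.path(dir, "features.csv.gz")))
  layout <- jsonlite::read_json(file.path(dir, "layout.json"))
  expect_equal(layout$feature_dim, 60)
  df <- read.csv(gzfile(file.path(dir, "features.csv.gz")))
  expect_equal(nrow(df), sum(vapply(recs, function(r) r$graph$n_atoms, 0L)))
})
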