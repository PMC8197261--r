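test_that("model building is deterministic and allocates only enabled paths", {
  cfg <- model_config(feature_dim = 8, seed = 42)
  m1 <- build_model(cfg)
  m2 <- build_model(cfg)
  expect_identical(m1$params, m2$params)

  node_only <- build_model(model_config(feature_dim = 8, paths = "node"))
  expect_false(any(grepl("^(edge|3d)\\.", names(node_only$params))))
  expect_error(model_config(paths = character()), "one path")
})

test_that("parameter counts match the shape arithmetic", {
  m <- build_model(model_config(feature_dim = 1, n_layers = 1,
                                paths = "node"))
  expect_equal(as.integer(count_parameters(m)), 7L)

  m3d <- build_model(model_config(feature_dim = 1, n_layers = 1,
                                  paths = "3d"))
  expect_equal(as.integer(count_parameters(m3d)), 9L)

  # unshared layers: doubling T doubles each path's parameter count
  for (p in c("node", "edge", "3d")) {
    c1 <- attr(count_parameters(build_model(
      model_config(feature_dim = 3, n_layers = 1, paths = p))), "breakdown")
    c2 <- attr(count_parameters(build_model(
      model_config(feature_dim = 3, n_layers = 2, paths = p))), "breakdown")
    expect_equal(c2[[p]], 2 * c1[[p]])
  }

  # fixed-mode edge values are constants, not parameters
  lrn <- count_parameters(build_model(model_config(feature_dim = 3,
                                                   paths = "edge",
                                                   edge_mode = "learned")))
  fix <- count_parameters(build_model(model_config(feature_dim = 3,
                                                   paths = "edge",
                                                   edge_mode = "fixed")))
  expect_equal(as.integer(lrn) - as.integer(fix), 6L * 2L)  # (w, c) per layer
})

test_that("forward reduces to the head bias at zero weights and is permutation invariant", {
  g <- rand_graph(3)
  cfg <- model_config(feature_dim = 5, seed = 3)
  m <- build_model(cfg)
  g5 <- shrink_features(g, 5, 3)
  mz <- m
  for (nm in names(mz$params)) mz$params[[nm]] <- mz$params[[nm]] * 0
  mz$params[["head.b_fc"]] <- 1.25
  expect_equal(as.numeric(forward(mz, g5)), 1.25)

  out <- forward(m, g5)
  set.seed(90)
  perm <- sample(g$n_atoms)
  gp <- permute_graph(g, perm)
  gp$H_init <- g5$H_init[perm, , drop = FALSE]
  gp$cache <- mpgcn:::graph_pair_cache(gp$n_atoms, gp$bonds, gp$C)
  outp <- forward(m, gp)
  expect_equal(as.numeric(outp), as.numeric(out), tolerance = 1e-10)
  # attention weights permute with the atoms
  expect_equal(attr(outp, "alpha"),
               attr(out, "alpha")[perm, , drop = FALSE], tolerance = 1e-10)
})

test_that("forward is translation invariant with the 3D path enabled", {
  g <- rand_graph(5)
  m <- build_model(model_config(feature_dim = 4, paths = c("node", "3d"),
                                seed = 5))
  g4 <- shrink_features(g, 4, 5)
  out <- as.numeric(forward(m, g4))
  gs <- molecular_graph(g$elements, g$bonds, g$C + 7, num_h = g$num_h,
                        charge = g$charge)
  gs$H_init <- g4$H_init
  gs$cache <- mpgcn:::graph_pair_cache(gs$n_atoms, gs$bonds, gs$C)
  expect_equal(as.numeric(forward(m, gs)), out, tolerance = 1e-10)
  g_nc <- shrink_features(molecular_graph(g$elements, g$bonds), 4, 5)
  expect_error(forward(m, g_nc), "coordinates")
})

test_that("two disconnected copies double the molecular vector (sum readout)", {
  # linear regime: nonnegative weights keep every relu input >= 0
  g <- molecular_graph(c("C", "O"), data.frame(i = 1, j = 2,
                                               type = "SINGLE"))
  M <- 3
  g1 <- shrink_features(g, M, 31)
  m <- build_model(model_config(feature_dim = M, paths = "node", seed = 1))
  for (nm in names(m$params))
    m$params[[nm]] <- abs(m$params[[nm]])
  m$params[["head.b_fc"]] <- 0
  g2 <- molecular_graph(c("C", "O", "C", "O"),
                        data.frame(i = c(1, 3), j = c(2, 4),
                                   type = "SINGLE"))
  g2$H_init <- rbind(g1$H_init, g1$H_init)
  g2$cache <- mpgcn:::graph_pair_cache(4, g2$bonds, NULL)
  expect_equal(as.numeric(forward(m, g2)), 2 * as.numeric(forward(m, g1)),
               tolerance = 1e-10)
})

test_that("single-path forward equals the path module plus readout and head", {
  g <- rand_graph(9)
  M <- 4
  g4 <- shrink_features(g, M, 9)
  for (p in c("node", "edge", "3d")) {
    m <- build_model(model_config(feature_dim = M, paths = p, n_layers = 2,
                                  seed = 17))
    H <- g4$H_init
    upd <- switch(p, node = node_path_update, edge = edge_path_update,
                  `3d` = threed_path_update)
    for (t in 1:2) H <- upd(H, g4, mpgcn:::layer_par(m, p, t))
    manual <- sum(m$params[["head.W_fc"]] * colSums(H)) +
      m$params[["head.b_fc"]]
    expect_equal(as.numeric(forward(m, g4)), manual, tolerance = 1e-10)
  }
})

test_that("batched forward agrees with per-graph forward", {
  graphs <- lapply(1:6, function(s) shrink_features(rand_graph(s), 4, s))
  m <- build_model(model_config(feature_dim = 4, seed = 2))
  single <- vapply(graphs, function(g) as.numeric(forward(m, g)), 0)
  batched <- mpgcn:::batch_forward_cached(m, mpgcn:::build_batch(graphs))$raw
  expect_equal(batched, single, tolerance = 1e-12)
})

test_that("every-layer placement runs and differs from final placement generically", {
  g <- shrink_features(rand_graph(11), 4, 11)
  cfg_f <- model_config(feature_dim = 4, seed = 4)
  cfg_e <- model_config(feature_dim = 4, aggregate_placement = "every_layer",
                        seed = 4)
  mf <- build_model(cfg_f)
  me <- build_model(cfg_e)
  expect_identical(mf$params, me$params)  # same seed, same shapes
  expect_false(isTRUE(all.equal(as.numeric(forward(me, g)),
                                as.numeric(forward(mf, g)))))
})

test_that("checkpoints round-trip predictions exactly and validate on load", {
  m <- build_model(model_config(feature_dim = 6, seed = 13))
  # train-free param jitter so values are not just the seeded init
  set.seed(77)
  for (nm in m$trainable)
    m$params[[nm]] <- m$params[[nm]] + rnorm(length(m$params[[nm]]), 0, 0.1)
  m$scaler <- list(mean = 1.5, sd = 2.25)
  tmp <- withr::local_tempfile(fileext = ".json")
  save_checkpoint(m, tmp)
  m2 <- load_checkpoint(tmp)
  graphs <- lapply(1:10, function(s) shrink_features(rand_graph(s + 50), 6, s))
  for (g in graphs)
    expect_identical(as.numeric(forward(m2, g)), as.numeric(forward(m, g)))
  expect_identical(m2$scaler, m$scaler)

  # tampered feature_dim must be rejected
  obj <- jsonlite::read_json(tmp, simplifyVector = TRUE)
  obj$config$feature_dim <- 32
  tmp2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(obj, tmp2, auto_unbox = TRUE, null = "null")
  expect_error(load_checkpoint(tmp2), "values|names")

  obj$feature_layout <- "something-else"
  jsonlite::write_json(obj, tmp2, auto_unbox = TRUE, null = "null")
  expect_error(load_checkpoint(tmp2), "layout")

  # parameter-group names in the file match the count report groups
  ck <- jsonlite::read_json(tmp, simplifyVector = TRUE)
  bd <- attr(count_parameters(m), "breakdown")
  expect_true(all(names(bd) %in% sub("\\..*$", "", names(ck$params))))
})
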