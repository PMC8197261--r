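test_that("split sizes follow the floor rule with remainder to test", {
  recs <- as.list(1:100)
  sp <- split_dataset(recs, split_spec(base_seed = 5), trial = 1)
  expect_equal(lengths(sp[c("train", "valid", "test")]),
               c(train = 80L, valid = 10L, test = 10L))
  sp25 <- split_dataset(as.list(1:25), split_spec(base_seed = 5), trial = 1)
  expect_equal(lengths(sp25[c("train", "valid", "test")]),
               c(train = 20L, valid = 2L, test = 3L))
  # disjoint and exhaustive
  idx <- attr(sp25, "indices")
  expect_setequal(unlist(idx), 1:25)
  expect_equal(sum(lengths(idx)), 25)
  # reproducible per trial, different across trials
  sp2 <- split_dataset(recs, split_spec(base_seed = 5), trial = 1)
  expect_identical(attr(sp2, "indices"), attr(sp, "indices"))
  sp3 <- split_dataset(recs, split_spec(base_seed = 5), trial = 2)
  expect_false(identical(attr(sp3, "indices"), attr(sp, "indices")))
  expect_error(split_dataset(as.list(1:5), split_spec()), "at least 10")
})

test_that("mse loss follows its definition and quadratic scaling", {
  expect_equal(mse_loss(c(1, 2), c(1, 2)), 0)
  expect_equal(mse_loss(c(0, 0), c(1, -1)), 1)
  r <- c(0.3, -1.2, 0.5)
  expect_equal(mse_loss(2 * r, rep(0, 3)), 4 * mse_loss(r, rep(0, 3)))
  expect_error(mse_loss(numeric(), numeric()), "empty")
})

test_that("early stopping fires after exactly `patience` sub-threshold improvements", {
  h <- 1 - cumsum(c(0, rep(0.00005, 10)))  # epochs 2..11 improve by 5e-5
  expect_false(should_stop(h[1:10], 10, 1e-4))
  expect_true(should_stop(h, 10, 1e-4))
  # one good improvement inside the window resets the verdict
  h2 <- h
  h2[7] <- h2[6] - 0.01
  h2[8:11] <- h2[7] - cumsum(rep(0.00005, 4))
  expect_false(should_stop(h2, 10, 1e-4))
  # shorter than patience: never stop
  expect_false(should_stop(c(1, 0.9, 0.8), 10, 1e-4))
  # min_delta = 0 with strictly decreasing losses never stops
  dec <- 1 / (1:50)
  expect_false(should_stop(dec, 10, 0))
  # non-improving plateau stops
  expect_true(should_stop(rep(1, 11), 10, 1e-4))
})

small_task <- function(n = 60, mode = "composition", seed = 1) {
  make_dataset(synth_spec(n_molecules = n, mode = mode, noise_sd = 0.1,
                          seed = seed))
}

test_that("stage 1 trains each path and leaves the aggregator untouched", {
  recs <- small_task()
  sp <- split_dataset(recs, split_spec(base_seed = 1), 1)
  model <- build_model(model_config(paths = c("node", "edge"), seed = 2))
  agg_before <- model$params[grep("^agg\\.", names(model$params))]
  head_before <- model$params[grep("^head\\.", names(model$params))]
  tc <- train_config(max_epochs = 3, seed = 2)
  res <- train_stage1(model, sp$train, sp$valid, tc)
  expect_named(res$logs, c("node", "edge"))
  for (p in c("node", "edge")) {
    lg <- res$logs[[p]]
    expect_true(all(is.finite(lg$train_loss)))
    expect_lte(lg$stop_epoch, 3)
    # path parameters moved
    expect_false(identical(res$model$params[[paste0(p, ".1.W_", substr(p, 1, 1))]],
                           model$params[[paste0(p, ".1.W_", substr(p, 1, 1))]]))
  }
  expect_identical(res$model$params[grep("^agg\\.", names(res$model$params))],
                   agg_before)
  expect_identical(res$model$params[grep("^head\\.", names(res$model$params))],
                   head_before)
  # stage-1 training reduces the training loss on the composition task
  lg <- res$logs$node
  expect_lt(tail(lg$train_loss, 1), lg$train_loss[1])
})

test_that("stage 2 freezes path parameters bitwise and trains agg + head", {
  recs <- small_task()
  sp <- split_dataset(recs, split_spec(base_seed = 3), 1)
  tc <- train_config(max_epochs = 3, seed = 3)
  model <- build_model(model_config(paths = c("node", "edge"), seed = 3))
  s1 <- train_stage1(model, sp$train, sp$valid, tc)
  path_names <- grep("^(node|edge)\\.", names(s1$model$params), value = TRUE)
  before <- s1$model$params[path_names]
  s2 <- train_stage2(s1$model, sp$train, sp$valid, tc)
  expect_identical(s2$model$params[path_names], before)
  expect_false(identical(s2$model$params[["head.W_fc"]],
                         s1$model$params[["head.W_fc"]]))
  expect_equal(s2$log$stage, "stage2")
})

test_that("single-path stage 2 trains only the head (degenerate aggregation)", {
  recs <- small_task(40)
  sp <- split_dataset(recs, split_spec(base_seed = 4), 1)
  tc <- train_config(max_epochs = 2, seed = 4)
  model <- build_model(model_config(paths = "node", seed = 4))
  s1 <- train_stage1(model, sp$train, sp$valid, tc)
  s2 <- train_stage2(s1$model, sp$train, sp$valid, tc)
  expect_setequal(s2$log$updated, c("head.W_fc", "head.b_fc"))
})

test_that("seeded runs are fully deterministic end to end", {
  recs <- small_task(40)
  sp <- split_dataset(recs, split_spec(base_seed = 6), 1)
  mc <- model_config(paths = c("node", "edge"), seed = 6)
  tc <- train_config(max_epochs = 3, seed = 6)
  f1 <- mpgcn:::fit_two_stage(sp$train, sp$valid, mc, tc)
  f2 <- mpgcn:::fit_two_stage(sp$train, sp$valid, mc, tc)
  expect_identical(f1$model$params, f2$model$params)
  expect_identical(f1$logs, f2$logs)
})

test_that("trial protocol aggregates per-trial metrics into means", {
  recs <- small_task(40)
  mc <- model_config(paths = "node", seed = 1)
  tc <- train_config(max_epochs = 2, seed = 1)
  tr <- run_trials(recs, mc, tc, split_spec(n_trials = 3, base_seed = 9))
  expect_length(tr$results, 3)
  maes <- vapply(tr$results, function(r) r$metrics[["mae"]], 0)
  expect_equal(unname(tr$mean[["mae"]]), mean(maes))
  # single-trial mean equals that trial's metric
  tr1 <- run_trials(recs, mc, tc, split_spec(n_trials = 1, base_seed = 9))
  expect_equal(tr1$mean[["mae"]], tr1$results[[1]]$metrics[["mae"]])
  expect_equal(unname(tr1$sd[["mae"]]), 0)
  # identical base seeds give identical results
  tr2 <- run_trials(recs, mc, tc, split_spec(n_trials = 1, base_seed = 9))
  expect_identical(tr1$results, tr2$results)
})

test_that("the mpgcn front end fits, predicts, and exposes methods", {
  recs <- small_task(50)
  fit <- mpgcn(recs, model = model_config(paths = "node", seed = 3),
               training = train_config(max_epochs = 2, seed = 3))
  expect_s3_class(fit, "mpgcn")
  pred <- predict(fit, recs[1:5])
  expect_length(pred, 5)
  expect_true(all(is.finite(pred)))
  expect_length(residuals(fit), fit$n_train)
  cf <- coef(fit)
  expect_equal(length(cf), as.integer(count_parameters(fit$model)))
  expect_output(print(fit), "Multi-path")
  expect_output(print(summary(fit)), "training MAE")
  tmp <- withr::local_tempfile(fileext = ".png")
  grDevices::png(tmp); plot(fit); grDevices::dev.off()
  expect_true(file.exists(tmp))
})
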