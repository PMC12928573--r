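# Training loop contracts: learning progress, determinism, schedule
# degeneracies, ablation wiring.

small_benchmark <- function() {
  ds <- synth_dataset(n_drugs = 40, n_pairs = 200, noise = 0.1, seed = 19)
  split <- make_warm_split(ds$triplets, k = 5, seed = 4)
  list(ds = ds, split = split)
}

test_that("training reduces the supervised loss on a small benchmark", {
  b <- small_benchmark()
  cfg <- ddi_config(d = 16, graph = list(heads = 2, layers = 1),
                    seq = list(heads = 2, layers = 1),
                    train = list(epochs = 30, epochs_cl = 2, batch_size = 32),
                    seed = 6)
  fit <- train_model(b$ds$drugs, b$split, cfg)
  sup <- fit$history[fit$history$phase == "supervised", ]
  expect_lt(sup$loss[30], sup$loss[1])
  expect_true(all(is.finite(fit$history$loss)))
  expect_s3_class(fit$metrics, "metrics_report")
})

test_that("training is deterministic given the seed", {
  b <- small_benchmark()
  cfg <- ddi_config(d = 8, graph = list(heads = 2, layers = 1),
                    seq = list(heads = 2, layers = 1),
                    train = list(epochs = 4, epochs_cl = 2, batch_size = 32),
                    seed = 6)
  f1 <- train_model(b$ds$drugs, b$split, cfg)
  f2 <- train_model(b$ds$drugs, b$split, cfg)
  expect_identical(f1$metrics, f2$metrics)
  expect_identical(f1$test_scores, f2$test_scores)
})

test_that("a zero contrastive weight removes the contrastive gradient", {
  drugs <- tiny_drugs()
  cfg <- tiny_cfg(train = list(lambda_cl = 0))
  model <- ddi_model(build_token_vocab(drugs$smiles), feature_vocab(), cfg)
  cache <- crossddi:::.drug_cache(drugs, model)
  pairs <- data.frame(a = c(1L, 2L), b = c(3L, 4L), y = c(1, 0))
  joint <- crossddi:::.model_objective(model, cache, drugs$drug_id, pairs,
                                       phase = "joint")
  sup <- crossddi:::.model_objective(model, cache, drugs$drug_id, pairs,
                                     phase = "supervised")
  expect_equal(joint$loss, sup$bce)
  expect_equal(joint$grads$graph, sup$grads$graph, tolerance = 1e-12)
  expect_equal(joint$grads$seq, sup$grads$seq, tolerance = 1e-12)
})

test_that("ablation variants leave the disabled view untouched and share splits", {
  b <- small_benchmark()
  cfg <- ddi_config(d = 8, graph = list(heads = 2, layers = 1),
                    seq = list(heads = 2, layers = 1),
                    train = list(epochs = 3, epochs_cl = 1, batch_size = 32),
                    seed = 6)
  fits <- lapply(c("full", "no_graph_view", "no_sequence_view"),
                 run_ablation, drugs = b$ds$drugs, split = b$split, cfg = cfg)
  names(fits) <- c("full", "no_graph_view", "no_sequence_view")

  # untouched parameters equal a freshly initialised model's
  ref <- ddi_model(fits$no_graph_view$model$token_vocab, feature_vocab(),
                   fits$no_graph_view$model$cfg)
  expect_equal(fits$no_graph_view$model$params$graph, ref$params$graph)
  ref2 <- ddi_model(fits$no_sequence_view$model$token_vocab, feature_vocab(),
                    fits$no_sequence_view$model$cfg)
  expect_equal(fits$no_sequence_view$model$params$seq, ref2$params$seq)

  key <- function(f) paste(f$sets$test$drug_a, f$sets$test$drug_b,
                           f$sets$test$label)
  expect_identical(key(fits$full), key(fits$no_graph_view))
  expect_identical(key(fits$full), key(fits$no_sequence_view))
  expect_error(run_ablation("bogus", b$ds$drugs, b$split, cfg),
               "unknown variant")
})

test_that("prediction on new pairs works from a fitted model", {
  b <- small_benchmark()
  cfg <- ddi_config(d = 8, graph = list(heads = 2, layers = 1),
                    seq = list(heads = 2, layers = 1),
                    train = list(epochs = 2, epochs_cl = 1, batch_size = 32),
                    seed = 6)
  fit <- train_model(b$ds$drugs, b$split, cfg)
  te <- fit$sets$test[1:5, ]
  s <- predict_pairs(fit$model, b$ds$drugs, te)
  expect_length(s, 5L)
  expect_true(all(s > 0 & s < 1))
  rep <- evaluate_model(fit, b$ds$drugs, fit$sets$test)
  expect_equal(rep$n, nrow(fit$sets$test))
  # symmetrized scoring averages the two orientations
  m2 <- fit$model
  m2$cfg$predict$symmetrize <- TRUE
  rev_te <- te; rev_te$drug_a <- te$drug_b; rev_te$drug_b <- te$drug_a
  s_sym <- predict_pairs(m2, b$ds$drugs, te)
  s_sym_rev <- predict_pairs(m2, b$ds$drugs, rev_te)
  expect_equal(s_sym, s_sym_rev, tolerance = 1e-12)
})
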