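# A small scaled corpus shared by several blocks in this file.
scaled_corpus <- local({
  streams <- tiny_streams(n_subjects = 3, duration_s = 20, seed = 1)
  w <- segment_corpus(streams, "step")
  apply_scaler(fit_scaler(w), w)
})

test_that("model_config validates its ranges", {
  cfg <- model_config()
  expect_equal(cfg$n_units, 512L)
  expect_equal(cfg$dropout, 0.5)
  expect_equal(cfg$learning_rate, 0.001)
  expect_equal(cfg$batch_size, 32L)
  expect_equal(cfg$epochs, 30L)
  expect_true(cfg$bidirectional)
  expect_error(model_config(dropout = 1.5), "dropout")
  expect_error(model_config(dropout = 1), "dropout")
  expect_error(model_config(window_len = 150), "window_len")
  expect_error(model_config(learning_rate = 0), "learning_rate")
})

test_that("training rejects degenerate class structure", {
  one <- scaled_corpus[scaled_corpus$info$subject_id ==
                         scaled_corpus$info$subject_id[1]]
  cfg <- model_config(n_units = 4, epochs = 1, seed = 1)
  expect_error(train_classifier(cfg, one), "at least 2 classes")
  cfg2 <- model_config(n_units = 4, epochs = 1, n_classes = 5, seed = 1)
  expect_error(train_classifier(cfg2, scaled_corpus), "n_classes")
})

test_that("an untrained network emits near-uniform posteriors", {
  cfg <- model_config(n_units = 8, epochs = 0, seed = 5)
  m <- train_classifier(cfg, scaled_corpus)
  expect_equal(nrow(m$history), 0)
  out <- gaitreid:::predict_scores(m, scaled_corpus)
  C <- length(m$classes)
  expect_true(all(abs(out$scores - 1 / C) < 0.05))
  # rank-1 under symmetry: close to chance over many windows
  acc <- mean(m$classes[out$preds] == scaled_corpus$info$subject_id)
  expect_lt(abs(acc - 1 / C), 0.35)
})

test_that("prediction results are normalized distributions", {
  cfg <- model_config(n_units = 8, epochs = 1, seed = 2)
  m <- train_classifier(cfg, scaled_corpus)
  pr <- predict_window(m, window_matrix(scaled_corpus, 1))
  expect_s3_class(pr, "prediction_result")
  expect_equal(dim(pr$per_timestep), c(100, 3))
  expect_true(all(pr$per_timestep >= 0))
  expect_true(all(abs(rowSums(pr$per_timestep) - 1) < 1e-6))
  expect_lt(abs(sum(pr$aggregated) - 1), 1e-6)
  # mean aggregation is the arithmetic mean of per-timestep posteriors
  expect_equal(unname(pr$aggregated), unname(colMeans(pr$per_timestep)),
               tolerance = 1e-12)
  expect_equal(pr$predicted_class, m$classes[which.max(pr$aggregated)])
  expect_error(predict_window(m, matrix(0, 50, 6)), "timesteps")
})

test_that("vote aggregation tallies per-timestep argmaxes", {
  cfg <- model_config(n_units = 8, epochs = 1, seed = 2, aggregate = "vote")
  m <- train_classifier(cfg, scaled_corpus)
  pr <- predict_window(m, window_matrix(scaled_corpus, 5))
  votes <- tabulate(max.col(pr$per_timestep, ties.method = "first"), 3)
  expect_equal(unname(pr$aggregated), votes / 100)
  expect_equal(sum(pr$aggregated), 1)
})

test_that("batched training path equals the reference cell stack forward", {
  cfg <- model_config(n_units = 5, epochs = 1, seed = 3, dropout = 0.4)
  m <- train_classifier(cfg, scaled_corpus)
  stack <- as_gru_stack(m)
  for (i in c(1, 7)) {
    wmat <- window_matrix(scaled_corpus, i)
    feats <- bidirectional_forward(stack, wmat, m$config)
    logits <- feats %*% m$params[["head.W"]] +
      matrix(m$params[["head.b"]], nrow(feats), ncol = 3, byrow = TRUE)
    p <- exp(logits - apply(logits, 1, max))
    p <- p / rowSums(p)
    pr <- predict_window(m, wmat)
    expect_equal(unname(pr$per_timestep), unname(p), tolerance = 1e-10)
  }
})

test_that("training is deterministic under a fixed seed", {
  cfg <- model_config(n_units = 4, epochs = 1, seed = 9)
  m1 <- train_classifier(cfg, scaled_corpus)
  m2 <- train_classifier(cfg, scaled_corpus)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)
  cfg2 <- model_config(n_units = 4, epochs = 1, seed = 10)
  m3 <- train_classifier(cfg2, scaled_corpus)
  expect_false(identical(m1$params, m3$params))
})

test_that("relu candidate activation trains and predicts", {
  cfg <- model_config(n_units = 4, epochs = 1, seed = 4,
                      activation = "relu")
  m <- train_classifier(cfg, scaled_corpus)
  pr <- predict_window(m, window_matrix(scaled_corpus, 2))
  expect_true(all(abs(rowSums(pr$per_timestep) - 1) < 1e-6))
})

test_that("model weights round-trip through disk", {
  cfg <- model_config(n_units = 4, epochs = 1, seed = 6)
  m <- train_classifier(cfg, scaled_corpus)
  prefix <- file.path(withr::local_tempdir(), "model")
  write_model(m, prefix)
  back <- read_model(prefix)
  expect_equal(back$params, m$params)
  expect_equal(back$classes, m$classes)
  p1 <- predict_window(m, window_matrix(scaled_corpus, 3))
  p2 <- predict_window(back, window_matrix(scaled_corpus, 3))
  expect_equal(p1$per_timestep, p2$per_timestep)
})

test_that("5 well-separated subjects are re-identified above 95% held out", {
  # 5 subjects at 1.0, 1.25, 1.5, 1.75, 2.0 Hz, 90 s each, 64 units,
  # 10 epochs — the desk-scale regression fixture.
  streams <- fixture_streams(n_subjects = 5, duration_s = 90, seed = 1)
  w <- segment_corpus(streams, "step")
  split <- half_split(w, seed = 1)
  scaler <- fit_scaler(split$train)
  cfg <- model_config(n_units = 64, epochs = 10, seed = 1)
  m <- train_classifier(cfg, apply_scaler(scaler, split$train))
  # learning sanity: loss decreases over training
  expect_lt(m$history$loss[10], m$history$loss[1])
  out <- gaitreid:::predict_scores(m, apply_scaler(scaler, split$test))
  acc <- mean(m$classes[out$preds] == split$test$info$subject_id)
  expect_gte(acc, 0.95)
})
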