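# CNN construction, training, evaluation bookkeeping, and streaming
# inference.

test_that("softmax outputs are probabilities and initialization is seeded", {
  m1 <- build_model(model_config(seed = 3))
  m2 <- build_model(model_config(seed = 3))
  m3 <- build_model(model_config(seed = 4))
  expect_identical(m1$weights, m2$weights)
  expect_false(identical(m1$weights, m3$weights))

  set.seed(1)
  x <- matrix(rnorm(129 * 124), 129, 124)
  p <- predict(m1, x)
  expect_equal(dim(p), c(1L, 5L))
  expect_lt(abs(sum(p) - 1), 1e-6)
  expect_true(all(p >= 0))
})

test_that("batch forward equals per-item forward passes", {
  model <- build_model(model_config(seed = 2))
  set.seed(2)
  inputs <- lapply(1:6, function(i) matrix(rnorm(129 * 124), 129, 124))
  batch <- predict(model, inputs)
  singles <- do.call(rbind, lapply(inputs, function(x) predict(model, x)))
  expect_equal(batch, singles, tolerance = 1e-12)
})

test_that("shape mismatches and degenerate manifests are rejected", {
  model <- build_model(model_config(seed = 1))
  expect_error(predict(model, matrix(0, 64, 64)))
  one_class <- build_dataset(20, labels = "cough", seed = 1)
  expect_error(train_model(model, one_class), "single class")
  no_test <- build_dataset(20, seed = 1)
  no_test$split[no_test$split == "test"] <- "train"
  expect_error(train_model(model, no_test), "'test' is empty")
})

test_that("training converges on the separable synthetic dataset", {
  fit <- test_fit()
  # loss decreases over the run (seeded, separable data)
  expect_lt(fit$train_loss[length(fit$train_loss)], fit$train_loss[1])
  expect_true(all(diff(fit$train_loss) < 0.1))  # no divergence
  expect_gte(fit$accuracy, 0.8)
  # trained model beats the analytic band-energy baseline
  te <- manifest_clips(test_dataset(), "test")
  base_acc <- mean(predict(test_baseline(), te$clips) == te$labels)
  expect_gt(fit$accuracy, base_acc - 1e-12)
})

test_that("training is reproducible under a fixed seed", {
  small <- build_dataset(50, seed = 8)
  f1 <- train_model(build_model(model_config(seed = 5)), small,
                    epochs = 1, seed = 5)
  f2 <- train_model(build_model(model_config(seed = 5)), small,
                    epochs = 1, seed = 5)
  expect_identical(f1$model$weights, f2$model$weights)
  expect_identical(f1$train_loss, f2$train_loss)
})

test_that("confusion-matrix bookkeeping identities hold exactly", {
  classes <- cough_classes()
  set.seed(31)
  true <- sample(classes, 300, replace = TRUE)
  # perfect predictor: diagonal matrix, accuracy 1
  cm <- confusion_matrix(true, true, classes)
  expect_equal(sum(cm), 300)
  expect_equal(sum(diag(cm)), 300)
  # majority-class predictor on balanced data: accuracy = 1/K
  bal <- rep(classes, each = 60)
  cm2 <- confusion_matrix(bal, rep("cough", 300), classes)
  expect_equal(sum(diag(cm2)) / sum(cm2), 0.2)
  # row sums recount the per-class truth
  pred <- sample(classes, 300, replace = TRUE)
  cm3 <- confusion_matrix(true, pred, classes)
  expect_equal(rowSums(cm3), table(factor(true, classes)),
               ignore_attr = TRUE)
  # evaluate_model reports trace/sum as accuracy
  ev <- evaluate_model(test_model(), test_dataset(), split = "val")
  expect_equal(ev$accuracy, sum(diag(ev$confusion)) / sum(ev$confusion))
  expect_equal(sum(ev$confusion), ev$n)
})

test_that("checkpoints restore an identical model", {
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(test_model(), path)
  back <- load_model(path)
  expect_identical(back$weights, test_model()$weights)
  x <- frontend_pipeline(synth_clip("music", 12), gate = FALSE)
  expect_identical(predict(back, x), predict(test_model(), x))
  saveRDS(list(container = "other"), path)
  expect_error(load_model(path), "checkpoint")
})

test_that("streaming detection finds and merges cough events", {
  model <- test_model()
  # one burst at t = 2 in a 10 s ambient stream: exactly one event near 2 s
  st <- synth_stream(10, data.frame(label = "cough", time = 2.0), seed = 5)
  ev <- classify_stream(st, model)
  expect_equal(nrow(ev), 1)
  expect_lte(ev$start, 2.0)
  expect_gte(ev$end, 2.0)
  expect_equal(ev$label, "cough")

  # two bursts 0.3 s apart merge; 3 s apart stay separate
  close_pair <- synth_stream(10, data.frame(label = c("cough", "cough"),
                                            time = c(2, 2.3)), seed = 6)
  far_pair <- synth_stream(10, data.frame(label = c("cough", "cough"),
                                          time = c(2, 5)), seed = 7)
  expect_equal(nrow(classify_stream(close_pair, model)), 1)
  ev2 <- classify_stream(far_pair, model)
  expect_equal(nrow(ev2), 2)
  expect_true(all(ev2$end > ev2$start))
  expect_true(all(ev2$start[-1] > ev2$end[-nrow(ev2)]))  # non-overlapping

  # pure silence: zero events; every window gated
  silent <- classify_stream(numeric(10 * 16000), model)
  expect_equal(nrow(silent), 0)
  expect_true(all(attr(silent, "windows")$gated))

  # shorter than one window: warning, no events
  expect_warning(out <- classify_stream(numeric(1000), model), "shorter")
  expect_equal(nrow(out), 0)
})

test_that("metrics and confusion plots are written", {
  fit <- test_fit()
  js <- withr::local_tempfile(fileext = ".json")
  cs <- withr::local_tempfile(fileext = ".csv")
  png <- withr::local_tempfile(fileext = ".png")
  write_metrics(fit, json_path = js, csv_path = cs)
  m <- jsonlite::fromJSON(js)
  expect_equal(m$accuracy, fit$accuracy)
  expect_true(file.exists(cs))
  plot_confusion(fit$confusion, png)
  expect_gt(file.size(png), 0)
})
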