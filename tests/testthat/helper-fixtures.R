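# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

# Noise-free warm-up of the default calibration scene (identity sensor).
default_warmup <- function() {
  if (is.null(.fixtures$warmup)) {
    .fixtures$warmup <- simulate_warmup(thermal_scene(), sensor_model(),
                                        duration = 120)
  }
  .fixtures$warmup
}

# A modest synthetic dataset and a model trained on it, shared by the
# classifier, streaming, and monitor tests (80 clips per class).
test_dataset <- function() {
  if (is.null(.fixtures$dataset)) {
    .fixtures$dataset <- build_dataset(400, seed = 3L)
  }
  .fixtures$dataset
}

test_fit <- function() {
  if (is.null(.fixtures$fit)) {
    .fixtures$fit <- train_model(build_model(model_config(seed = 1L)),
                                 test_dataset(), epochs = 4L, seed = 1L)
  }
  .fixtures$fit
}

test_model <- function() test_fit()$model

# Baseline fitted on the same train split, evaluated where needed.
test_baseline <- function() {
  if (is.null(.fixtures$baseline)) {
    tr <- manifest_clips(test_dataset(), "train")
    .fixtures$baseline <- fit_band_energy_baseline(tr$clips, tr$labels)
  }
  .fixtures$baseline
}

# A free localhost TCP port (bind an ephemeral server socket to find one).
free_port <- function() {
  for (p in sample(20000:45000, 20)) {
    srv <- tryCatch(serverSocket(p), error = function(e) NULL)
    if (!is.null(srv)) {
      close(srv)
      return(p)
    }
  }
  stop("no free port found")
}
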