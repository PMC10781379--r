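# R surface of the cough classifier: model construction, training and
# evaluation over dataset manifests, confusion-matrix bookkeeping, and
# streaming-window inference with event merging.

#' Classifier configuration
#'
#' The fixed small-network architecture: two 3x3 convolution stages (16 then
#' 32 filters, each followed by 2x2 max-pool downsampling), dropout on the
#' flattened features, one 64-unit hidden dense stage, and a softmax output
#' over the class set.
#'
#' @param input_shape `(rows, cols)` of the model input (129, 124).
#' @param conv_filters Filter counts of the two convolution stages.
#' @param dense_units Hidden dense width.
#' @param dropout Dropout rate on the flattened features during training.
#' @param classes Class labels (2 or 5 classes).
#' @param seed Parameter-initialization seed.
#' @return An object of class `model_config`.
#' @export
model_config <- function(input_shape = c(129L, 124L),
                         conv_filters = c(16L, 32L),
                         dense_units = 64L, dropout = 0.25,
                         classes = cough_classes(), seed = 42L) {
  if (!length(classes) %in% c(2L, 5L)) {
    stopf("classifier supports 2 or 5 classes, got %d", length(classes))
  }
  structure(list(input_shape = as.integer(input_shape),
                 conv_filters = as.integer(conv_filters),
                 dense_units = as.integer(dense_units),
                 dropout = dropout, classes = classes,
                 seed = as.integer(seed)),
            class = "model_config")
}

flat_features <- function(cfg) {
  h1 <- cfg$input_shape[1] - 2L; w1 <- cfg$input_shape[2] - 2L
  q1h <- h1 %/% 2L; q1w <- w1 %/% 2L
  h2 <- q1h - 2L; w2 <- q1w - 2L
  (h2 %/% 2L) * (w2 %/% 2L) * cfg$conv_filters[2]
}

#' Build (initialize) the classifier
#'
#' Deterministic He-normal parameter initialization under the config seed:
#' two builds with the same seed have identical parameters.
#'
#' @param cfg A [model_config()].
#' @return An object of class `cough_cnn` with fields `config`, `weights`.
#' @export
#' @examples
#' m <- build_model(model_config(seed = 1))
#' dim(m$weights$W1)
build_model <- function(cfg = model_config()) {
  c1 <- cfg$conv_filters[1]; c2 <- cfg$conv_filters[2]
  f <- flat_features(cfg)
  k <- length(cfg$classes)
  he <- function(nr, nc, fan_in) {
    matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
  }
  weights <- with_local_seed(cfg$seed, list(
    W1 = he(9L, c1, 9),
    b1 = numeric(c1),
    W2 = he(9L * c1, c2, 9 * c1),
    b2 = numeric(c2),
    Wd = he(f, cfg$dense_units, f),
    bd = numeric(cfg$dense_units),
    # softmax layer: Glorot-style scale keeps initial logits moderate
    Wo = matrix(stats::rnorm(cfg$dense_units * k, 0,
                             sqrt(1 / cfg$dense_units)),
                cfg$dense_units, k),
    bo = numeric(k)
  ))
  structure(list(config = cfg, weights = weights, trained = FALSE),
            class = "cough_cnn")
}

#' @export
print.cough_cnn <- function(x, ...) {
  cfg <- x$config
  n_par <- sum(vapply(x$weights, length, numeric(1)))
  cat(sprintf(
    "cough classifier CNN: %dx%d input -> conv(%d) -> conv(%d) -> dense(%d) -> %d classes\n",
    cfg$input_shape[1], cfg$input_shape[2], cfg$conv_filters[1],
    cfg$conv_filters[2], cfg$dense_units, length(cfg$classes)))
  cat(sprintf("  %s parameters, %s\n", format(n_par, big.mark = ","),
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

# Stack model inputs (list of matrices or a 3-d array) into an H x W x N array.
as_input_array <- function(inputs, cfg) {
  if (is.array(inputs) && length(dim(inputs)) == 3) return(inputs)
  if (is.matrix(inputs)) inputs <- list(inputs)
  arr <- array(0, c(cfg$input_shape, length(inputs)))
  for (i in seq_along(inputs)) arr[, , i] <- inputs[[i]]
  arr
}

#' Class probabilities for prepared inputs
#'
#' @param object A `cough_cnn`.
#' @param inputs A `model_input`, a list of them, or an `H x W x N` array.
#' @param type `"prob"` for the probability matrix, `"class"` for labels.
#' @param ... Unused.
#' @return `N x K` probability matrix (rows sum to 1) or a label vector.
#' @export
predict.cough_cnn <- function(object, inputs, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  arr <- as_input_array(inputs, object$config)
  p <- .cnn_forward_cpp(object$weights, arr)
  colnames(p) <- object$config$classes
  if (type == "class") object$config$classes[max.col(p, "first")] else p
}

# Clips -> prepared input array + integer labels for the C++ core.
clips_to_training_arrays <- function(clips, labels, cfg) {
  inputs <- lapply(clips, function(cl) {
    frontend_pipeline(cl, gate = FALSE)
  })
  list(x = as_input_array(inputs, cfg),
       y = as.integer(match(labels, cfg$classes) - 1L))
}

#' Train the classifier on a dataset manifest
#'
#' Trains on the manifest's train split with per-epoch feedback on the
#' validation split, then reports accuracy and the confusion matrix on the
#' test split. Fully seeded: shuffling and dropout derive from `seed`.
#'
#' @param model A [build_model()] result.
#' @param manifest A [build_dataset()] manifest.
#' @param epochs,batch_size,lr Optimization settings (Adam).
#' @param seed Training seed.
#' @param verbose Print per-epoch progress.
#' @return A `cough_train_result`: the trained `model`, per-epoch
#'   `train_loss` and `val_accuracy`, and test-split `accuracy`,
#'   `confusion` (rows = true class, columns = predicted), `n_test`.
#' @export
train_model <- function(model, manifest, epochs = 4L, batch_size = 32L,
                        lr = 1e-3, seed = 1L, verbose = FALSE) {
  cfg <- model$config
  for (s in c("train", "val", "test")) {
    if (!any(manifest$split == s)) stopf("manifest split '%s' is empty", s)
  }
  if (length(unique(manifest$label[manifest$split == "train"])) < 2) {
    stopf("degenerate labels: training split holds a single class")
  }
  tr <- manifest_clips(manifest, "train")
  va <- manifest_clips(manifest, "val")
  tr_arr <- clips_to_training_arrays(tr$clips, tr$labels, cfg)
  va_arr <- clips_to_training_arrays(va$clips, va$labels, cfg)
  fit <- .cnn_train_cpp(model$weights, tr_arr$x, tr_arr$y,
                        va_arr$x, va_arr$y,
                        as.integer(epochs), as.integer(batch_size), lr,
                        cfg$dropout, as.integer(seed), isTRUE(verbose))
  model$weights <- fit$weights
  model$trained <- TRUE
  te <- manifest_clips(manifest, "test")
  ev <- evaluate_model(model, te$clips, te$labels)
  structure(list(model = model,
                 train_loss = as.numeric(fit$train_loss),
                 val_accuracy = as.numeric(fit$val_accuracy),
                 accuracy = ev$accuracy, confusion = ev$confusion,
                 n_test = ev$n),
            class = "cough_train_result")
}

#' @export
print.cough_train_result <- function(x, ...) {
  cat(sprintf("training run: %d epochs, final loss %.4f\n",
              length(x$train_loss), x$train_loss[length(x$train_loss)]))
  cat(sprintf("  validation accuracy: %s\n",
              paste(sprintf("%.3f", x$val_accuracy), collapse = " ")))
  cat(sprintf("  test accuracy: %.3f on %d clips\n", x$accuracy, x$n_test))
  invisible(x)
}

#' Confusion matrix with fixed class order
#'
#' Rows are true classes, columns predicted; entries sum to the evaluation
#' size and accuracy equals `trace / sum`.
#'
#' @param true,pred Label vectors.
#' @param classes Class order.
#' @return Integer K x K matrix.
#' @export
confusion_matrix <- function(true, pred, classes) {
  t1 <- factor(true, levels = classes)
  t2 <- factor(pred, levels = classes)
  unclass(table(true = t1, predicted = t2))
}

#' Evaluate the classifier on labelled clips
#'
#' @param model A trained `cough_cnn`.
#' @param clips List of `audio_clip`s (or a manifest, with `split`).
#' @param labels True labels (ignored when `clips` is a manifest).
#' @param split Split name when `clips` is a manifest.
#' @return `list(accuracy, confusion, n)`.
#' @export
evaluate_model <- function(model, clips, labels = NULL, split = "test") {
  if (inherits(clips, "dataset_manifest")) {
    mc <- manifest_clips(clips, split)
    clips <- mc$clips
    labels <- mc$labels
  }
  arr <- clips_to_training_arrays(clips, labels, model$config)
  p <- .cnn_forward_cpp(model$weights, arr$x)
  pred <- model$config$classes[max.col(p, "first")]
  cm <- confusion_matrix(labels, pred, model$config$classes)
  list(accuracy = sum(diag(cm)) / sum(cm), confusion = cm, n = sum(cm))
}

#' Streaming cough detection over a sliding window
#'
#' Slides 1 s windows with 50% overlap across the stream, skips
#' silence-gated windows, classifies the rest, and merges consecutive
#' cough-labelled windows into events (a new event starts only after a gap
#' longer than `debounce_gap` seconds). The overlap is what keeps a cough
#' that straddles a window boundary detectable.
#'
#' @param samples Numeric stream at 16 kHz mono (or an `audio_clip`).
#' @param model A trained `cough_cnn`.
#' @param window,hop Window length and hop in seconds.
#' @param gate_threshold Silence-gate RMS threshold.
#' @param debounce_gap Maximum silent gap (s) bridged inside one event.
#' @return A data frame of events (`start`, `end`, `label`, `confidence`)
#'   with the per-window decisions in `attr(, "windows")`. Streams shorter
#'   than one window yield zero events with a warning.
#' @export
classify_stream <- function(samples, model, window = 1.0, hop = 0.5,
                            gate_threshold = 0.01, debounce_gap = 0.5) {
  if (inherits(samples, "audio_clip")) samples <- samples$samples
  rate <- 16000L
  win_n <- as.integer(window * rate)
  hop_n <- as.integer(hop * rate)
  events <- data.frame(start = numeric(0), end = numeric(0),
                       label = character(0), confidence = numeric(0))
  if (length(samples) < win_n) {
    warning("stream shorter than one analysis window; no events")
    attr(events, "windows") <- data.frame()
    return(events)
  }
  starts <- seq(0L, length(samples) - win_n, by = hop_n)
  wins <- data.frame(start = starts / rate, end = (starts + win_n) / rate,
                     gated = FALSE, label = NA_character_,
                     p_cough = NA_real_)
  inputs <- list()
  keep <- integer(0)
  for (i in seq_along(starts)) {
    clip <- audio_clip(samples[(starts[i] + 1L):(starts[i] + win_n)], rate)
    if (silence_gate(clip, gate_threshold)) {
      wins$gated[i] <- TRUE
    } else {
      keep <- c(keep, i)
      inputs[[length(inputs) + 1L]] <-
        prepare_model_input(compute_spectrogram(normalize_peak(clip)))
    }
  }
  if (length(keep) > 0) {
    p <- predict(model, inputs)
    wins$label[keep] <- model$config$classes[max.col(p, "first")]
    ci <- match("cough", model$config$classes)
    wins$p_cough[keep] <- p[, ci]
  }
  cough_idx <- which(!is.na(wins$label) & wins$label == "cough")
  ev <- list()
  if (length(cough_idx) > 0) {
    cur <- c(cough_idx[1], cough_idx[1])
    flush <- function(rng) {
      data.frame(start = wins$start[rng[1]], end = wins$end[rng[2]],
                 label = "cough",
                 confidence = max(wins$p_cough[rng[1]:rng[2]], na.rm = TRUE))
    }
    for (i in cough_idx[-1]) {
      if (wins$start[i] - wins$end[cur[2]] <= debounce_gap) {
        cur[2] <- i
      } else {
        ev[[length(ev) + 1L]] <- flush(cur)
        cur <- c(i, i)
      }
    }
    ev[[length(ev) + 1L]] <- flush(cur)
    events <- do.call(rbind, ev)
  }
  attr(events, "windows") <- wins
  events
}

#' Save / load a classifier checkpoint
#'
#' Version-stamped container (RDS) holding the config and weights.
#'
#' @param model A `cough_cnn`.
#' @param path Checkpoint path.
#' @return `path` invisibly; `load_model()` returns the `cough_cnn`.
#' @export
save_model <- function(model, path) {
  saveRDS(list(container = "feverwatch-cnn", version = 1L,
               config = model$config, weights = model$weights,
               trained = model$trained), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$container, "feverwatch-cnn")) {
    stopf("not a feverwatch model checkpoint")
  }
  structure(list(config = obj$config, weights = obj$weights,
                 trained = isTRUE(obj$trained)),
            class = "cough_cnn")
}

#' Write evaluation metrics as JSON and CSV
#'
#' @param result A `cough_train_result`.
#' @param json_path,csv_path Output paths (either may be `NULL`).
#' @return Invisibly, the metrics list.
#' @export
write_metrics <- function(result, json_path = NULL, csv_path = NULL) {
  metrics <- list(accuracy = result$accuracy, n_test = result$n_test,
                  train_loss = result$train_loss,
                  val_accuracy = result$val_accuracy,
                  confusion = result$confusion)
  if (!is.null(json_path)) {
    jsonlite::write_json(metrics, json_path, auto_unbox = TRUE, digits = NA,
                         matrix = "rowmajor")
  }
  if (!is.null(csv_path)) {
    utils::write.csv(as.data.frame(result$confusion), csv_path,
                     row.names = FALSE)
  }
  invisible(metrics)
}

#' Plot a confusion matrix to PNG
#'
#' @param cm Confusion matrix (rows true, columns predicted).
#' @param file PNG path; `NULL` draws on the current device.
#' @return `file` invisibly.
#' @export
plot_confusion <- function(cm, file = NULL) {
  if (!is.null(file)) {
    grDevices::png(file, width = 640, height = 560)
    on.exit(grDevices::dev.off())
  }
  k <- nrow(cm)
  graphics::image(seq_len(k), seq_len(k), t(cm[k:1, , drop = FALSE]),
                  col = grDevices::hcl.colors(64, "Blues", rev = TRUE),
                  axes = FALSE, xlab = "predicted", ylab = "true")
  graphics::axis(1, seq_len(k), colnames(cm))
  graphics::axis(2, seq_len(k), rev(rownames(cm)), las = 2)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    graphics::text(j, k - i + 1, cm[i, j])
  }
  invisible(file)
}
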