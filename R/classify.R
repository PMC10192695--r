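#' Stack per-channel Hilbert spectra into a classifier input
#'
#' Concatenates the 23 per-channel Hilbert spectrum grids of one segment
#' along a channel axis (channel x frequency x time tensor) and applies
#' per-segment global min-max normalization to \[0, 1\]. A constant (zero
#' range) stack maps to all zeros.
#'
#' @param hs_list List of exactly 23 `hilbert_spectrum` objects with
#'   identical grids.
#' @param label Optional segment label ("ictal"/"interictal").
#' @return A `spectrogram_stack`: 23 x freq-bins x time-bins array with a
#'   `label` attribute.
#' @export
render_stack <- function(hs_list, label = NULL) {
  if (!is.list(hs_list) || length(hs_list) != 23L)
    stopf("`hs_list` must contain exactly 23 Hilbert spectra (got %d)",
          length(hs_list))
  dims <- lapply(hs_list, function(h) {
    if (!inherits(h, "hilbert_spectrum")) stopf("all elements must be hilbert_spectrum")
    dim(h$grid)
  })
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1L)
    stopf("all channel spectra must share the same grid")
  edges <- hs_list[[1L]]
  for (h in hs_list)
    if (!isTRUE(all.equal(h$freq_edges, edges$freq_edges)) ||
        !isTRUE(all.equal(h$time_edges, edges$time_edges)))
      stopf("all channel spectra must share the same bin edges")
  nt <- dims[[1L]][1L]; nf <- dims[[1L]][2L]
  arr <- array(0, dim = c(23L, nf, nt))
  for (ch in seq_len(23L)) arr[ch, , ] <- t(hs_list[[ch]]$grid)
  lo <- min(arr); hi <- max(arr)
  arr <- if (hi > lo) (arr - lo) / (hi - lo) else array(0, dim = dim(arr))
  structure(arr, label = label, class = "spectrogram_stack")
}

#' Render the stack of a segment directly
#'
#' @param seg An `eeg_segment`.
#' @param ... Passed to [hilbert_spectrum()].
#' @return A [render_stack()] result labelled with the segment's label.
#' @export
segment_stack <- function(seg, ...) {
  render_stack(segment_spectra(seg, ...), label = seg$label)
}

#' Classifier configuration
#'
#' The small convolutional network used on spectrogram stacks:
#' conv(32, 3x3)-ReLU-maxpool(2x2)-conv(64, 3x3)-ReLU-maxpool(2x2)-dropout-
#' dense-softmax(2), trained with Adam on an 80/20 split.
#'
#' @param filters Two conv filter counts (default c(32, 64)).
#' @param dense Dense layer width (default 64).
#' @param dropout Dropout rate on the flattened conv features (default 0.5).
#' @param lr Adam learning rate (default 1e-3).
#' @param epochs Training epochs (default 20).
#' @param batch_size Minibatch size (default 16).
#' @param split Training fraction in (0, 1) (default 0.8).
#' @param seed Integer seed fixing initialization, shuffling, dropout and
#'   the split.
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(filters = c(32L, 64L), dense = 64L,
                              dropout = 0.5, lr = 1e-3, epochs = 20L,
                              batch_size = 16L, split = 0.8, seed = 1L) {
  if (length(filters) != 2L) stopf("`filters` must have length 2")
  if (split <= 0 || split >= 1) stopf("`split` must be in (0, 1)")
  structure(list(filters = as.integer(filters), dense = as.integer(dense),
                 dropout = dropout, lr = lr, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), split = split,
                 seed = as.integer(seed)),
            class = "classifier_config")
}

# flatten a list of stacks into the (C, H, W, n) array the C++ core expects
stacks_to_array <- function(stacks) {
  d <- dim(stacks[[1L]])
  X <- array(0, dim = c(d, length(stacks)))
  for (k in seq_along(stacks)) X[, , , k] <- stacks[[k]]
  X
}

#' Train the convolutional seizure classifier
#'
#' Trains on a seed-deterministic stratified `split` fraction of the stacks
#' and evaluates on the held-out remainder. The positive class is "ictal".
#'
#' @param stacks List of `spectrogram_stack`s.
#' @param labels Optional character vector; defaults to the stacks' label
#'   attributes.
#' @param cfg A [classifier_config()].
#' @return An `ictal_cnn`: list with `weights`, `cfg`, `dims`,
#'   `train_idx`, `test_idx`, `loss` (per-epoch training loss), and
#'   `holdout` ([compute_metrics()] on the held-out split).
#' @export
train_classifier <- function(stacks, labels = NULL, cfg = classifier_config()) {
  if (length(stacks) < 4L) stopf("need at least 2 examples per class")
  if (is.null(labels))
    labels <- vapply(stacks, function(s) attr(s, "label") %||% NA_character_, "")
  if (anyNA(labels)) stopf("labels missing; pass `labels` or labelled stacks")
  y <- match(labels, c("interictal", "ictal")) - 1L
  if (anyNA(y)) stopf("labels must be 'ictal' or 'interictal'")
  if (length(unique(y)) < 2L) stopf("need both classes present")
  if (min(table(y)) < 2L) stopf("need at least 2 examples per class")

  n <- length(stacks)
  train_idx <- with_seed(cfg$seed, {
    idx <- unlist(lapply(unique(y), function(cl) {
      members <- which(y == cl)
      sample(members, max(1L, round(cfg$split * length(members))))
    }))
    sort(idx)
  })
  test_idx <- setdiff(seq_len(n), train_idx)
  d <- dim(stacks[[1L]])
  X <- stacks_to_array(stacks[train_idx])
  fit <- cnn_train_cpp(as.numeric(X), c(d, length(train_idx)),
                       y[train_idx], cfg$filters[1L], cfg$filters[2L],
                       cfg$dense, cfg$dropout, cfg$lr, cfg$epochs,
                       cfg$batch_size, cfg$seed)
  model <- structure(list(weights = fit[c("W1", "b1", "W2", "b2",
                                          "Wf1", "bf1", "Wf2", "bf2")],
                          loss = fit$loss, cfg = cfg, dims = d,
                          train_idx = train_idx, test_idx = test_idx,
                          classes = c("interictal", "ictal")),
                     class = "ictal_cnn")
  if (length(test_idx) > 0L && length(unique(y[test_idx])) == 2L) {
    scores <- predict(model, stacks[test_idx])
    model$holdout <- compute_metrics(scores, y[test_idx])
  }
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ictal_cnn <- function(x, ...) {
  cat(sprintf("<ictal_cnn> conv(%d,%d) dense(%d), %d epochs, %d train / %d test\n",
              x$cfg$filters[1], x$cfg$filters[2], x$cfg$dense, x$cfg$epochs,
              length(x$train_idx), length(x$test_idx)))
  if (!is.null(x$holdout))
    cat(sprintf("  held-out accuracy %.3f, AUC %.3f\n",
                x$holdout$accuracy, x$holdout$auc))
  invisible(x)
}

#' Predict ictal probabilities for spectrogram stacks
#'
#' @param object An `ictal_cnn`.
#' @param stacks List of `spectrogram_stack`s (same grid as training).
#' @param ... Unused.
#' @return Numeric vector of class-"ictal" probabilities.
#' @export
predict.ictal_cnn <- function(object, stacks, ...) {
  d <- dim(stacks[[1L]])
  if (!all(d == object$dims)) stopf("stack dimensions do not match the model")
  X <- stacks_to_array(stacks)
  p <- cnn_predict_cpp(object$weights, as.numeric(X), c(d, length(stacks)),
                       object$cfg$filters[1L], object$cfg$filters[2L],
                       object$cfg$dense)
  p[, 2L]
}

#' Binary classification metrics
#'
#' Confusion counts at a probability threshold plus threshold-free AUC.
#' Sensitivity = TP/(TP+FN), specificity = TN/(TN+FP), accuracy =
#' (TP+TN)/total, F1 = 2TP/(2TP+FP+FN). AUC is the rank statistic over all
#' positive/negative score pairs with ties counted 1/2.
#'
#' @param scores Class-1 (ictal) probabilities.
#' @param labels 0/1 vector (or "interictal"/"ictal").
#' @param threshold Decision threshold (default 0.5).
#' @return An `eval_metrics` list: sensitivity, specificity, accuracy, f1,
#'   auc, TP, FP, TN, FN.
#' @export
compute_metrics <- function(scores, labels, threshold = 0.5) {
  if (is.character(labels) || is.factor(labels))
    labels <- as.integer(as.character(labels) == "ictal")
  if (length(scores) != length(labels)) stopf("scores and labels differ in length")
  if (length(unique(labels)) < 2L)
    stopf("both classes must be present (AUC undefined otherwise)")
  pred <- as.integer(scores >= threshold)
  TP <- sum(pred == 1 & labels == 1); FP <- sum(pred == 1 & labels == 0)
  TN <- sum(pred == 0 & labels == 0); FN <- sum(pred == 0 & labels == 1)
  npos <- sum(labels == 1); nneg <- sum(labels == 0)
  r <- rank(scores)                     # midranks handle ties as 1/2
  auc <- (sum(r[labels == 1]) - npos * (npos + 1) / 2) / (npos * nneg)
  structure(list(sensitivity = TP / (TP + FN),
                 specificity = TN / (TN + FP),
                 accuracy = (TP + TN) / length(labels),
                 f1 = 2 * TP / (2 * TP + FP + FN),
                 auc = auc,
                 TP = TP, FP = FP, TN = TN, FN = FN),
            class = "eval_metrics")
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat(sprintf("<eval_metrics> acc %.3f sens %.3f spec %.3f f1 %.3f auc %.3f\n",
              x$accuracy, x$sensitivity, x$specificity, x$f1, x$auc))
  cat(sprintf("  TP %d FP %d TN %d FN %d\n", x$TP, x$FP, x$TN, x$FN))
  invisible(x)
}
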