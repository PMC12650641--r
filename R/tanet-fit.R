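# User-facing fitting interface: tanet() wraps model construction, an
# internal stratified validation split, and the training loop, returning a
# classed object with the familiar print/summary/predict/plot methods.

#' Fit a triple-attention EEG emotion classifier
#'
#' Builds the network for the given configuration, holds out a stratified
#' validation fraction (or uses supplied validation data), and trains with
#' the seeded AdamW loop. Labels may be integers, factors or character;
#' the mapping to class indices is stored for prediction.
#'
#' @param de,psd feature tensors (trials, bands, channels, windows).
#' @param labels per-trial class labels.
#' @param config a [tanet_config()]; inferred dimensions are checked.
#' @param train a [train_config()].
#' @param validation a fraction in (0, 1) for an internal stratified
#'   hold-out, or a list with `de`, `psd`, `labels`.
#' @param model_seed seed for parameter initialisation.
#' @param verbose print per-epoch progress.
#' @return An object of class `"tanet"`: the trained `model`, training
#'   `history`, class `levels`, and the final validation `report`.
#' @export
tanet <- function(de, psd, labels, config = tanet_config(),
                  train = train_config(), validation = 0.1,
                  model_seed = 1L, verbose = FALSE) {
  stopifnot(length(dim(de)) == 4, identical(dim(de), dim(psd)),
            dim(de)[1] == length(labels))
  lv <- if (is.factor(labels)) levels(labels) else sort(unique(labels))
  y <- as.integer(factor(labels, levels = lv))
  if (length(lv) != config$n_classes) {
    stop("found ", length(lv), " classes but the configuration expects ",
         config$n_classes)
  }
  sub4 <- function(a, idx) array(a[idx, , , , drop = FALSE],
                                 c(length(idx), dim(a)[-1]))
  if (is.numeric(validation) && length(validation) == 1) {
    sp <- stratified_split(y, ratio = 1 - validation, seed = train$seed)
    # stratified_split's "test" fraction is the held-out validation part
    val <- list(de = sub4(de, sp$test), psd = sub4(psd, sp$test),
                labels = y[sp$test])
    trn <- list(de = sub4(de, sp$train), psd = sub4(psd, sp$train),
                labels = y[sp$train])
  } else {
    trn <- list(de = de, psd = psd, labels = y)
    val <- list(de = validation$de, psd = validation$psd,
                labels = as.integer(factor(validation$labels, levels = lv)))
  }
  model <- tanet_model(config, seed = model_seed)
  fit <- tanet_train(model, trn, val, train, verbose = verbose)
  probs <- predict_probs(fit$model, val$de, val$psd)
  obj <- list(model = fit$model, history = fit$history, levels = lv,
              config = config, train_config = train,
              report = evaluation_report(probs, val$labels))
  class(obj) <- "tanet"
  obj
}

#' @export
print.tanet <- function(x, ...) {
  cfg <- x$config
  cat("Triple-attention EEG emotion classifier\n")
  cat(sprintf("  layout %s: %d bands x %d channels x %d windows -> %d classes\n",
              cfg$layout, cfg$n_bands, cfg$eeg_channels, cfg$windows,
              cfg$n_classes))
  cat(sprintf("  %s trainable parameters\n",
              format(count_trainable_parameters(x$model), big.mark = ",")))
  cat(sprintf("  trained %d epochs; best validation accuracy %.4f\n",
              nrow(x$history), max(x$history$val_acc)))
  invisible(x)
}

#' @export
summary.tanet <- function(object, ...) {
  print(object)
  cat("\nValidation metrics:\n")
  print(object$report)
  cat("\nRow-normalised confusion matrix (rows = true class):\n")
  cm <- normalize_confusion(object$report$confusion)
  dimnames(cm) <- list(object$levels, object$levels)
  print(round(cm, 3))
  invisible(object)
}

#' Predict emotion classes or probabilities
#'
#' @param object a fitted `"tanet"` object.
#' @param de,psd feature tensors (trials, bands, channels, windows).
#' @param type `"class"` or `"prob"`.
#' @param ... unused.
#' @return Predicted labels (on the original level set) or a probability
#'   matrix with one column per class.
#' @export
predict.tanet <- function(object, de, psd, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  probs <- predict_probs(object$model, de, psd)
  colnames(probs) <- as.character(object$levels)
  if (type == "prob") return(probs)
  object$levels[max.col(probs, ties.method = "first")]
}

#' Plot training history
#'
#' Accuracy and loss curves for the training and validation sets.
#'
#' @param x a fitted `"tanet"` object.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.tanet <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::matplot(h$epoch, cbind(h$train_acc, h$val_acc), type = "l",
                    lty = 1, col = c("grey40", "firebrick"),
                    xlab = "epoch", ylab = "accuracy", main = "accuracy", ...)
  graphics::legend("bottomright", c("train", "validation"), lty = 1,
                   col = c("grey40", "firebrick"), bty = "n")
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("grey40", "firebrick"),
                    xlab = "epoch", ylab = "loss", main = "loss", ...)
  invisible(x)
}
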