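#' Classifier configuration
#'
#' Settings of the convolutional topic classifier.  Two scratch backbone
#' presets are built in: `"tiny"` (8/16 conv filters, 16 hidden units) —
#' the desk-scale default used throughout the tests — and `"small"`
#' (16/32 filters, 32 hidden units).  Both share the topology
#' conv3x3–ReLU–pool / conv3x3–ReLU–pool / global-average-pool / dense /
#' sigmoid, trained with Adam on binary cross-entropy with early stopping
#' on validation loss.
#'
#' @param backbone `"tiny"` or `"small"`.
#' @param lr learning rate (default 1e-3).
#' @param batch_size minibatch size (default 16).
#' @param max_epochs training cap (default 150).
#' @param patience early-stopping patience in epochs (default 10).
#' @param side,work_len image geometry handed to [encode_dataset()].
#' @param aggregate how participant probabilities combine into a triad
#'   probability: `"mean"` (default) or `"vote"` (majority).
#' @param seed integer training seed.
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(backbone = c("tiny", "small"),
                              lr = 1e-3, batch_size = 16,
                              max_epochs = 150, patience = 10,
                              side = 64, work_len = 256,
                              aggregate = c("mean", "vote"),
                              seed = 1L) {
  backbone <- match.arg(backbone)
  aggregate <- match.arg(aggregate)
  stopifnot(lr > 0, batch_size >= 1, max_epochs >= 1, patience >= 1,
            side >= 8, work_len >= 2)
  widths <- switch(backbone,
                   tiny = c(f1 = 8L, f2 = 16L, h = 16L),
                   small = c(f1 = 16L, f2 = 32L, h = 32L))
  structure(list(backbone = backbone, widths = widths, lr = lr,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 side = as.integer(side), work_len = as.integer(work_len),
                 aggregate = aggregate, seed = as.integer(seed)),
            class = "classifier_config")
}

# stack a list of gaf_image into an N x (side^2 * 3) matrix
images_to_matrix <- function(images) {
  do.call(rbind, lapply(images, function(im) as.vector(unclass(im))))
}

#' Fit the convolutional classifier on GADF images
#'
#' @param images_train,images_val lists of `gaf_image` (equal side).
#' @param y_train,y_val 0/1 labels per image.
#' @param config a [classifier_config()].
#' @return An object of class `faudyn_cnn` with elements `weights`,
#'   `epochs`, `best_val_loss`, `history`.
#' @export
cnn_fit <- function(images_train, y_train, images_val, y_val, config) {
  stopifnot(inherits(config, "classifier_config"),
            length(images_train) == length(y_train),
            length(images_val) == length(y_val))
  if (length(unique(y_train)) < 2)
    stop("training fold contains a single class")
  side <- dim(images_train[[1]])[1]
  w <- config$widths
  set.seed(config$seed)
  fit <- cnn_train_cpp(images_to_matrix(images_train), as.numeric(y_train),
                       images_to_matrix(images_val), as.numeric(y_val),
                       side, 3L, w["f1"], w["f2"], w["h"],
                       config$lr, config$batch_size, config$max_epochs,
                       config$patience)
  structure(list(weights = fit$weights, side = side,
                 epochs = fit$epochs, best_val_loss = fit$best_val_loss,
                 history = data.frame(epoch = seq_along(fit$train_loss),
                                      train_loss = fit$train_loss,
                                      val_loss = fit$val_loss),
                 config = config),
            class = "faudyn_cnn")
}

#' @export
print.faudyn_cnn <- function(x, ...) {
  cat(sprintf("faudyn CNN (%s backbone): %d epochs, best val loss %.4f\n",
              x$config$backbone, x$epochs, x$best_val_loss))
  invisible(x)
}

#' Predict class probabilities for GADF images
#'
#' @param object a `faudyn_cnn`.
#' @param images list of `gaf_image`.
#' @param ... unused.
#' @return Numeric vector of P(condition = 1) per image.
#' @export
predict.faudyn_cnn <- function(object, images, ...) {
  p <- as.numeric(cnn_predict_cpp(object$weights,
                                  images_to_matrix(images),
                                  object$side, 3L))
  names(p) <- names(images)
  p
}
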