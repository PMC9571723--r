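# Patch color classification: a deterministic nearest-centroid rule (the
# default), a compact trainable softmax network, and the representative-color
# vote over the selected patches.

.classifier_output <- function(probs, code, confidence) {
  structure(list(probs = probs, code = code, confidence = confidence),
            class = "classifier_output")
}

#' @export
print.classifier_output <- function(x, ...) {
  cat("predicted ", x$code, " (confidence ",
      format(x$confidence, digits = 3), ")\n", sep = "")
  invisible(x)
}

#' Nearest-centroid patch classification
#'
#' Computes the mean patch color in Lab and compares it with the 19 palette
#' centroids. Class probabilities are the softmax of the negative Lab
#' distances (unit temperature); the prediction is the nearest centroid,
#' demoted to `"unknown"` when even the nearest centroid is farther than its
#' tolerance radius.
#'
#' @param patch H x W x 3 patch array in \eqn{[0, 255]}.
#' @param palette a [palette_config()].
#' @return a `classifier_output`: `probs` (named, sums to 1), `code`
#'   (full code string or "unknown"), `confidence` (max probability).
#' @export
classify_nearest <- function(patch, palette = palette_config()) {
  if (length(patch) == 0L) stop("empty patch")
  lab <- rgb_to_lab(colMeans(matrix(patch, ncol = 3L)))
  d <- sqrt(rowSums(sweep(palette$centroids, 2, as.numeric(lab))^2))
  z <- exp(-(d - min(d)))          # shift-invariant softmax
  probs <- setNames(z / sum(z), palette$codes)
  k <- which.min(d)
  code <- if (d[k] > palette$radius[k]) "unknown" else palette$codes[k]
  .classifier_output(probs, code, max(probs))
}

## ---- trainable softmax network ----------------------------------------

#' Specification of the trainable patch-color network
#'
#' A compact single-hidden-layer softmax network fitted on patch color
#' summary features (mean Lab and per-channel Lab standard deviation), a
#' reduced-scale stand-in for a deep convolutional classifier. The full-size
#' reference architecture it scales down from is available as
#' [cnn_reference_spec()].
#'
#' @param hidden hidden units (default 24).
#' @param decay L2 weight decay (default 1e-4).
#' @param maxit maximum fitting iterations (default 300).
#' @param unknown_floor confidence floor below which the prediction is
#'   demoted to "unknown" (default 0.5).
#' @return object of class `color_net_spec`.
#' @export
color_net_spec <- function(hidden = 24L, decay = 1e-4, maxit = 300L,
                           unknown_floor = 0.5) {
  structure(list(hidden = as.integer(hidden), decay = decay,
                 maxit = as.integer(maxit), unknown_floor = unknown_floor),
            class = "color_net_spec")
}

#' Reference full-scale classifier architecture
#'
#' Constants of the full-size residual-network color classifier this package
#' scales down from: a ResNet-50 style extractor (7x7/2 convolution, 3x3/2
#' pooling, bottleneck residual groups repeated 3/4/6/3 up to 2048 channels,
#' 224 x 224 input) followed by fully connected layers 2048 -> 1000 -> 100
#' -> 19 and a softmax, trained with dropout 0.5, batch size 32, Adam
#' (beta1 0.9, beta2 0.999, eps 1e-8), learning rate 1e-4, at most 200
#' epochs, with the best-validation-epoch checkpoint kept. Provided as
#' documentation of the target architecture; the in-package trainable model
#' is [color_net_spec()].
#'
#' @return a named list of architecture and training constants.
#' @export
cnn_reference_spec <- function() {
  list(input = c(224L, 224L, 3L),
       stem = list(conv = c(7L, 7L), stride = 2L, channels = 64L),
       residual_blocks = list(repeats = c(3L, 4L, 6L, 3L),
                              bottleneck = c(1L, 3L, 1L),
                              out_channels = c(256L, 512L, 1024L, 2048L)),
       head = c(2048L, 1000L, 100L, 19L),
       softmax = TRUE,
       training = list(max_epochs = 200L, dropout = 0.5, batch_size = 32L,
                       optimizer = "adam", beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8, learning_rate = 1e-4,
                       checkpoint = "best-validation-epoch"))
}

.color_net_features <- function(patch) {
  lab <- rgb_to_lab(matrix(patch, ncol = 3L))
  c(colMeans(lab), apply(lab, 2, sd))
}

#' Train the compact patch-color network
#'
#' Fits the softmax network of [color_net_spec()] on labeled patches. A
#' validation split is held out and the per-iteration model is not
#' checkpointed (the underlying optimizer runs to convergence); the reported
#' validation accuracy plays the role of the best-epoch criterion at this
#' scale.
#'
#' @param patches list of H x W x 3 patch arrays.
#' @param labels character vector of full water-color codes.
#' @param spec a [color_net_spec()].
#' @param val_frac validation fraction (default 0.2).
#' @param seed RNG seed for the split and weight initialization.
#' @return object of class `color_net`: the fitted model, the class levels,
#'   and `val_accuracy`.
#' @export
train_color_net <- function(patches, labels, spec = color_net_spec(),
                            val_frac = 0.2, seed = 1L) {
  stopifnot(length(patches) == length(labels))
  bad <- setdiff(unique(labels), .WATER_CODES$code)
  if (length(bad))
    stop("labels outside the 19-code table: ", paste(bad, collapse = ", "))
  X <- t(vapply(patches, .color_net_features, numeric(6)))
  y <- factor(labels, levels = .WATER_CODES$code)
  set.seed(seed)
  n <- nrow(X)
  val <- sample.int(n, max(1L, round(val_frac * n)))
  ctr <- colMeans(X[-val, , drop = FALSE])
  scl <- apply(X[-val, , drop = FALSE], 2, sd)
  scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  fit <- nnet::nnet(Xs[-val, , drop = FALSE],
                    nnet::class.ind(y[-val]),
                    size = spec$hidden, decay = spec$decay,
                    maxit = spec$maxit, softmax = TRUE, trace = FALSE)
  pv <- predict(fit, Xs[val, , drop = FALSE])
  acc <- mean(levels(y)[max.col(pv)] == as.character(y[val]))
  structure(list(fit = fit, levels = levels(y), center = ctr, scale = scl,
                 spec = spec, val_accuracy = acc), class = "color_net")
}

#' Classify a patch with the trained network
#'
#' @param model a `color_net` from [train_color_net()].
#' @param patch H x W x 3 patch array.
#' @return a `classifier_output`; the prediction is "unknown" when the top
#'   probability falls below the spec's confidence floor.
#' @export
classify_net <- function(model, patch) {
  stopifnot(inherits(model, "color_net"))
  x <- (.color_net_features(patch) - model$center) / model$scale
  p <- as.numeric(predict(model$fit, matrix(x, nrow = 1L)))
  probs <- setNames(p / sum(p), model$levels)
  k <- which.max(probs)
  code <- if (probs[k] < model$spec$unknown_floor) "unknown"
          else model$levels[k]
  .classifier_output(probs, code, max(probs))
}

#' Confusion matrix of a classifier on labeled patches
#'
#' @param predicted,truth character vectors of codes.
#' @return row-normalized confusion matrix (true class in rows; rows sum to
#'   1).
#' @export
confusion_matrix <- function(predicted, truth) {
  lev <- .WATER_CODES$code
  tab <- table(factor(truth, levels = lev),
               factor(predicted, levels = c(lev, "unknown")))
  sweep(unclass(tab), 1, pmax(rowSums(tab), 1), "/")
}

## ---- representative color vote ----------------------------------------

#' Vote the representative pond color
#'
#' Decision over the classified top patches: (1) a code held by more than
#' half of them wins outright; (2) otherwise the unique most frequent code
#' wins; (3) if several codes tie for most frequent, the code of the single
#' highest-confidence patch wins, with an equal-confidence tie broken
#' deterministically by the lexicographically smallest code.
#'
#' @param outputs list of `classifier_output` objects.
#' @return the representative full code string.
#' @export
representative_color <- function(outputs) {
  if (length(outputs) == 0L) stop("no classifier outputs to vote over")
  codes <- vapply(outputs, `[[`, character(1), "code")
  conf <- vapply(outputs, `[[`, numeric(1), "confidence")
  tab <- table(codes)
  if (max(tab) > length(codes) / 2) return(names(tab)[which.max(tab)])
  modal <- names(tab)[tab == max(tab)]
  if (length(modal) == 1L) return(modal)
  best <- codes[conf == max(conf)]
  sort(best)[1]
}
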