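#' Describe a GAP-headed convolutional backbone
#'
#' The classifier is a stack of 3x3 convolution + ReLU blocks separated by
#' 2x2 max-pooling stages, followed by global average pooling (GAP) and a
#' two-node softmax head. Two presets are provided:
#'
#' * `"vgg19"` — the canonical 16-convolution / 5-pool feature extractor
#'   (stages of 2, 2, 4, 4, 4 convolutions with 64, 128, 256, 512, 512
#'   channels), producing a 7x7x512 feature tensor from a 224x224x3 input.
#' * `"mini"` — the same contract at desk scale: 2 convolutions per stage
#'   with channels ramping 8, 16, 32, ..., capped at 32. Identical shape
#'   laws and head, a tiny fraction of the parameters.
#'
#' Each pooling stage halves the spatial side (floor division), so the
#' feature-map side is `floor(input_size / 2^n_pool_stages)`.
#'
#' @param preset `"mini"` or `"vgg19"`
#' @param input_size square input side in pixels (default 224)
#' @param n_pool_stages number of pooling stages (default 5; the `"vgg19"`
#'   preset requires 5)
#' @return an object of class `"backbone_spec"`
#' @examples
#' backbone_spec("mini", input_size = 64, n_pool_stages = 3)
#' @export
backbone_spec <- function(preset = c("mini", "vgg19"), input_size = 224,
                          n_pool_stages = 5L) {
  preset <- match.arg(preset)
  n_pool_stages <- as.integer(n_pool_stages)
  if (n_pool_stages < 1L) stop("n_pool_stages must be >= 1")
  if (preset == "vgg19") {
    if (n_pool_stages != 5L) stop("the vgg19 preset has exactly 5 pooling stages")
    convs <- c(2L, 2L, 4L, 4L, 4L)
    channels <- c(64L, 128L, 256L, 512L, 512L)
  } else {
    convs <- rep(2L, n_pool_stages)
    channels <- as.integer(pmin(8 * 2^(seq_len(n_pool_stages) - 1), 32))
  }
  side <- as.integer(input_size %/% 2^n_pool_stages)
  if (side < 1L) {
    stop("input_size ", input_size, " collapses below 1 px after ",
         n_pool_stages, " pooling stages")
  }
  structure(list(preset = preset, input_size = as.integer(input_size),
                 n_pool_stages = n_pool_stages, convs_per_stage = convs,
                 channels = channels, channels_out = channels[n_pool_stages],
                 feature_side = side),
            class = "backbone_spec")
}

#' @export
print.backbone_spec <- function(x, ...) {
  cat("Backbone spec (", x$preset, ")\n", sep = "")
  cat("  input:", x$input_size, "x", x$input_size, "x 3\n")
  cat("  stages:", x$n_pool_stages, "( convs:",
      paste(x$convs_per_stage, collapse = ","), "; channels:",
      paste(x$channels, collapse = ","), ")\n")
  cat("  feature tensor F:", x$feature_side, "x", x$feature_side, "x",
      x$channels_out, "\n")
  invisible(x)
}

#' Build a GAP-headed convolutional classifier
#'
#' Instantiates the feature extractor described by a [backbone_spec()] plus a
#' global-average-pooling layer and a two-node softmax classification head
#' (nodes ordered non-failure, failure). Random initialisation is
#' He-scaled Gaussian and fully determined by `seed`. Externally trained
#' weights (e.g. an ImageNet-pretrained VGG-19 feature extractor) can be
#' plugged in via `weights`; no pretrained weights ship with the package.
#'
#' @param spec a [backbone_spec()]
#' @param init `"random"` or `"pretrained_vgg19"`; the latter requires the
#'   vgg19 preset and a `weights` list
#' @param seed integer seed for random initialisation
#' @param weights optional parameter tree (as found in `$params` of a fitted
#'   model) to plug in, required when `init = "pretrained_vgg19"`
#' @return an object of class `"emb_cnn"`
#' @examples
#' m <- build_model(backbone_spec("mini", input_size = 32, n_pool_stages = 3))
#' m
#' @export
build_model <- function(spec, init = c("random", "pretrained_vgg19"),
                        seed = 0L, weights = NULL) {
  init <- match.arg(init)
  if (!inherits(spec, "backbone_spec")) stop("spec must be a backbone_spec")
  if (init == "pretrained_vgg19") {
    if (spec$preset != "vgg19") {
      stop("pretrained_vgg19 initialisation requires the vgg19 preset")
    }
    if (is.null(weights)) {
      stop("pretrained_vgg19 initialisation requires a `weights` parameter tree; ",
           "none is bundled with the package")
    }
  }
  set.seed(seed)
  params <- list(conv = list(), head = NULL)
  cin <- 3L
  l <- 0L
  for (s in seq_len(spec$n_pool_stages)) {
    for (j in seq_len(spec$convs_per_stage[s])) {
      l <- l + 1L
      params$conv[[l]] <- init_conv(cin, spec$channels[s])
      cin <- spec$channels[s]
    }
  }
  params$head <- list(
    W = matrix(stats::rnorm(spec$channels_out * 2L,
                            sd = sqrt(1 / spec$channels_out)),
               spec$channels_out, 2L),
    b = numeric(2L))
  if (!is.null(weights)) params <- modifyList(params, weights)
  structure(list(spec = spec, params = params, history = NULL,
                 best_epoch = NA_integer_, init = init, seed = seed),
            class = "emb_cnn")
}

# Prepare one raw image for the network: error on wrong channel count,
# centre-crop when larger than the input size, reject when smaller.
prepare_input <- function(model, img) {
  d <- dim(img)
  if (length(d) != 3 || d[3] != 3) {
    stop("expected an H x W x 3 RGB array, got dims ", paste(d, collapse = "x"))
  }
  size <- model$spec$input_size
  if (d[1] < size || d[2] < size) {
    stop("image (", d[1], "x", d[2], ") smaller than model input size ", size)
  }
  if (d[1] > size || d[2] > size) img <- center_crop(img, size) else img
}

#' Predict failure probability, feature tensor and deep feature for one ROI
#'
#' Runs a single ROI through the network in evaluation mode (centre crop,
#' no augmentation). Returns the two-class Bernoulli prediction, the
#' last-pool feature tensor F, and the length-C GAP deep feature.
#'
#' @param model an `"emb_cnn"`
#' @param image an H x W x 3 array with values in \[0, 1\]
#' @return a list with `prediction` (named list `p_N`, `p_F`),
#'   `feature` (h x w x C array), and `deep` (length-C numeric)
#' @export
predict_roi <- function(model, image) {
  img <- prepare_input(model, image)
  fwd <- net_forward(model, list(img), train = FALSE)
  h <- fwd$h
  list(
    prediction = list(p_N = fwd$probs[1, 1], p_F = fwd$probs[1, 2]),
    feature = array(fwd$fmat, c(h, fwd$w, ncol(fwd$fmat))),
    deep = as.numeric(fwd$deep[1, ])
  )
}

#' Predict over a set of ROI images
#'
#' Batched evaluation-mode inference. `type = "prob"` returns a data frame of
#' class probabilities; `"deep"` returns the N x C matrix of GAP deep
#' features; `"all"` additionally returns the feature tensors.
#'
#' @param object an `"emb_cnn"`
#' @param images a list of H x W x 3 arrays (or a single array)
#' @param type `"prob"`, `"deep"` or `"all"`
#' @param batch_size images per forward pass
#' @param ... unused
#' @return see `type`
#' @export
predict.emb_cnn <- function(object, images, type = c("prob", "deep", "all"),
                            batch_size = 32L, ...) {
  type <- match.arg(type)
  if (is.array(images)) images <- list(images)
  images <- lapply(images, function(im) prepare_input(object, im))
  n <- length(images)
  probs <- matrix(0, n, 2L)
  deep <- matrix(0, n, object$spec$channels_out)
  feats <- if (type == "all") vector("list", n)
  for (start in seq(1L, n, by = batch_size)) {
    ix <- start:min(start + batch_size - 1L, n)
    fwd <- net_forward(object, images[ix], train = FALSE)
    probs[ix, ] <- fwd$probs
    deep[ix, ] <- fwd$deep
    if (type == "all") {
      hw <- fwd$h * fwd$w
      for (k in seq_along(ix)) {
        feats[[ix[k]]] <- array(fwd$fmat[(k - 1L) * hw + seq_len(hw), ],
                                c(fwd$h, fwd$w, ncol(fwd$fmat)))
      }
    }
  }
  pr <- data.frame(p_N = probs[, 1], p_F = probs[, 2])
  switch(type,
         prob = pr,
         deep = deep,
         all = list(prob = pr, deep = deep, feature = feats))
}

#' @export
print.emb_cnn <- function(x, ...) {
  np <- sum(vapply(x$params$conv, function(l) length(l$W) + length(l$b), 0)) +
    length(x$params$head$W) + length(x$params$head$b)
  cat("GAP-headed convolutional classifier (", x$spec$preset, " preset)\n",
      sep = "")
  cat("  parameters:", format(np, big.mark = ","), "\n")
  cat("  feature tensor:", x$spec$feature_side, "x", x$spec$feature_side, "x",
      x$spec$channels_out, "-> GAP ->", x$spec$channels_out,
      "-> softmax(2)\n")
  if (!is.null(x$history)) {
    cat("  trained:", nrow(x$history), "epochs; best epoch", x$best_epoch,
        "(val loss", format(min(x$history$val_loss), digits = 4), ")\n")
  } else {
    cat("  untrained (", x$init, " init, seed ", x$seed, ")\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.emb_cnn <- function(object, ...) {
  print(object)
  if (!is.null(object$history)) {
    cat("\nTraining history:\n")
    print(object$history, row.names = FALSE)
  }
  invisible(object)
}

#' Plot training and validation loss curves
#'
#' @param x a fitted `"emb_cnn"`
#' @param ... passed to [graphics::matplot()]
#' @export
plot.emb_cnn <- function(x, ...) {
  if (is.null(x$history)) stop("model has no training history")
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("steelblue", "darkorange"),
                    xlab = "epoch", ylab = "cross-entropy loss", ...)
  graphics::abline(v = x$best_epoch, lty = 3, col = "grey40")
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("steelblue", "darkorange"), bty = "n")
  invisible(x)
}
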