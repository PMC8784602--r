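# Training: cross-entropy loss, H&E stain-space augmentation, the geometric
# augmentation pipeline, and the Adam training loop with lowest-validation-
# loss checkpointing.

# Ruifrok-Johnston H&E(-DAB) stain vectors, rows normalised to unit length.
.he_stain_matrix <- local({
  M <- rbind(c(0.650, 0.704, 0.286),   # hematoxylin
             c(0.072, 0.990, 0.105),   # eosin
             c(0.268, 0.570, 0.776))   # residual (DAB) channel
  M / sqrt(rowSums(M^2))
})

#' Cross-entropy loss for a two-class prediction
#'
#' Computes `L = (1/|C|) * sum_c -y_c log(yhat_c)` with `|C| = 2`, the
#' label-set-normalised form used to train the classifier; predictions are
#' clamped at 1e-12 before the log. Vector inputs give a single scalar;
#' matrix inputs (one sample per row) give the mean loss over rows.
#'
#' @param y_onehot one-hot label vector (or matrix, samples in rows)
#' @param y_hat predicted distribution, same shape, entries in \[0, 1\]
#' @return nonnegative scalar loss
#' @examples
#' cross_entropy(c(1, 0), c(0.5, 0.5))  # log(2) / 2
#' @export
cross_entropy <- function(y_onehot, y_hat) {
  if (any(y_hat < 0 | y_hat > 1)) stop("predictions must lie in [0, 1]")
  y <- rbind(y_onehot)
  p <- pmax(rbind(y_hat), 1e-12)
  if (!all(dim(y) == dim(p))) stop("label and prediction shapes differ")
  mean(rowSums(-y * log(p)) / ncol(y))
}

#' Stain-augmentation parameters
#'
#' Per-stain-channel jitter applied in the hematoxylin/eosin optical-density
#' space obtained by color deconvolution: each channel is scaled by a factor
#' drawn uniformly from `[1 - sigma_alpha, 1 + sigma_alpha]` and shifted by a
#' bias from `[-sigma_beta, sigma_beta]`. Both zero gives the identity.
#'
#' @param sigma_alpha scale half-range (default 0.05)
#' @param sigma_beta bias half-range (default 0.05)
#' @export
stain_aug_params <- function(sigma_alpha = 0.05, sigma_beta = 0.05) {
  if (sigma_alpha < 0 || sigma_beta < 0) stop("stain jitter ranges must be >= 0")
  list(sigma_alpha = sigma_alpha, sigma_beta = sigma_beta)
}

# RGB [0,1] -> stain optical densities (H*W x 3), and back.
rgb_to_stain <- function(img) {
  od <- -log10(pmax(matrix(img, ncol = 3L), 1e-6))
  od %*% solve(.he_stain_matrix)
}

stain_to_rgb <- function(hed, dims) {
  rgb <- 10^(-(hed %*% .he_stain_matrix))
  array(clamp(rgb, 0, 1), dims)
}

#' Jitter an H&E image in stain space
#'
#' Color-deconvolves the image with the standard H&E stain matrix, applies
#' per-channel scale and bias drawn from [stain_aug_params()] ranges, and
#' recomposes to RGB (clipped to \[0, 1\]).
#'
#' @param image H x W x 3 array in \[0, 1\]
#' @param params a [stain_aug_params()]
#' @return augmented image array
#' @export
stain_augment <- function(image, params = stain_aug_params()) {
  hed <- rgb_to_stain(image)
  alpha <- stats::runif(3, 1 - params$sigma_alpha, 1 + params$sigma_alpha)
  beta <- stats::runif(3, -params$sigma_beta, params$sigma_beta)
  hed <- sweep(sweep(hed, 2, alpha, "*"), 2, beta, "+")
  stain_to_rgb(hed, dim(image))
}

#' Randomly augment a training ROI
#'
#' The training-time augmentation pipeline: a random square crop (224 px by
#' default), independent probability-0.5 horizontal and vertical flips, and
#' stain-space jitter. Each component is controlled by a flag; with all
#' flags off the image is returned unchanged. Randomness comes from the
#' current RNG stream.
#'
#' @param image H x W x 3 array in \[0, 1\]
#' @param crop,hflip,vflip,stain logical flags
#' @param crop_size random-crop side in pixels (default 224)
#' @param stain_params a [stain_aug_params()]
#' @return augmented image array
#' @export
augment <- function(image, crop = TRUE, hflip = TRUE, vflip = TRUE,
                    stain = TRUE, crop_size = 224L,
                    stain_params = stain_aug_params()) {
  d <- dim(image)
  if (crop) {
    if (d[1] < crop_size || d[2] < crop_size) {
      stop("image (", d[1], "x", d[2], ") smaller than crop size ", crop_size)
    }
    r0 <- sample.int(d[1] - crop_size + 1L, 1L) - 1L
    c0 <- sample.int(d[2] - crop_size + 1L, 1L) - 1L
    image <- image[r0 + seq_len(crop_size), c0 + seq_len(crop_size), ,
                   drop = FALSE]
  }
  if (hflip && stats::runif(1) < 0.5) {
    image <- image[, rev(seq_len(dim(image)[2])), , drop = FALSE]
  }
  if (vflip && stats::runif(1) < 0.5) {
    image <- image[rev(seq_len(dim(image)[1])), , , drop = FALSE]
  }
  if (stain) image <- stain_augment(image, stain_params)
  image
}

#' Bundle ROI images with labels and case ids
#'
#' @param images list of H x W x 3 arrays, or a character vector of PNG paths
#'   (loaded lazily by [train_cnn()] and friends via [load_images()])
#' @param labels character vector, `"failure"` / `"non_failure"`, one per ROI
#' @param case_ids character vector, one per ROI
#' @return a list of class `"roi_set"`
#' @export
roi_set <- function(images, labels, case_ids) {
  check_labels(labels)
  n <- if (is.character(images)) length(images) else length(images)
  if (length(labels) != n || length(case_ids) != n) {
    stop("images, labels and case_ids must have equal length")
  }
  structure(list(images = images, labels = labels,
                 case_ids = as.character(case_ids)),
            class = "roi_set")
}

#' Load PNG images referenced by a roi_set (or path vector)
#'
#' @param x a `"roi_set"` or character vector of paths
#' @return the same object with images materialised as arrays
#' @export
load_images <- function(x) {
  paths <- if (inherits(x, "roi_set")) x$images else x
  if (!is.character(paths)) return(x)
  imgs <- lapply(paths, function(p) {
    im <- png::readPNG(p)
    if (length(dim(im)) == 2) im <- array(rep(im, 3), c(dim(im), 3L))
    im[, , 1:3, drop = FALSE]
  })
  if (inherits(x, "roi_set")) {
    x$images <- imgs
    x
  } else {
    imgs
  }
}

#' Training configuration
#'
#' Defaults follow the reference protocol: Adam with a constant learning
#' rate of 1e-4, 100 epochs, batch size 32, and the full augmentation
#' pipeline (random 224 crop, flips, stain jitter). Validation loss is
#' computed on unaugmented centre crops at the end of every epoch, and the
#' parameters with the lowest validation loss are retained.
#'
#' @param epochs number of epochs (>= 1)
#' @param learning_rate Adam step size (> 0)
#' @param batch_size minibatch size
#' @param crop,hflip,vflip,stain augmentation flags
#' @param stain_params a [stain_aug_params()]
#' @param seed training seed (shuffling, augmentation draws)
#' @export
train_config <- function(epochs = 100L, learning_rate = 1e-4,
                         batch_size = 32L, crop = TRUE, hflip = TRUE,
                         vflip = TRUE, stain = TRUE,
                         stain_params = stain_aug_params(), seed = 0L) {
  if (epochs < 1) stop("epochs must be >= 1")
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  list(epochs = as.integer(epochs), learning_rate = learning_rate,
       batch_size = as.integer(batch_size), crop = crop, hflip = hflip,
       vflip = vflip, stain = stain, stain_params = stain_params,
       seed = as.integer(seed))
}

labels_to_onehot <- function(labels) {
  check_labels(labels)
  cbind(non_failure = as.numeric(labels == "non_failure"),
        failure = as.numeric(labels == "failure"))
}

# Evaluation-mode loss over a roi_set (centre crops, no augmentation).
eval_loss <- function(model, rset, batch_size = 32L) {
  imgs <- lapply(rset$images, function(im) prepare_input(model, im))
  y <- labels_to_onehot(rset$labels)
  n <- length(imgs)
  tot <- 0
  for (start in seq(1L, n, by = batch_size)) {
    ix <- start:min(start + batch_size - 1L, n)
    fwd <- net_forward(model, imgs[ix], train = FALSE)
    tot <- tot + cross_entropy(y[ix, , drop = FALSE], fwd$probs) * length(ix)
  }
  tot / n
}

#' Train a GAP-headed convolutional classifier
#'
#' Minimises the two-class cross-entropy with Adam, recording training and
#' validation loss at the end of every epoch and restoring the parameters
#' from the epoch with the lowest validation loss. Training and validation
#' sets must come from disjoint cases.
#'
#' @param model an `"emb_cnn"` from [build_model()]
#' @param train,val `"roi_set"` objects (images as arrays or PNG paths)
#' @param cfg a [train_config()]
#' @return the fitted `"emb_cnn"` with `$history` (epoch, train_loss,
#'   val_loss) and `$best_epoch`
#' @export
train_cnn <- function(model, train, val, cfg = train_config()) {
  train <- load_images(train)
  val <- load_images(val)
  if (!length(train$images) || !length(val$images)) {
    stop("empty training or validation set")
  }
  overlap <- intersect(unique(train$case_ids), unique(val$case_ids))
  if (length(overlap)) {
    stop("training and validation sets share case(s): ",
         paste(utils::head(overlap, 3), collapse = ", "))
  }
  size <- model$spec$input_size
  y_all <- labels_to_onehot(train$labels)
  n <- length(train$images)
  params <- model$params
  state <- adam_init(params)
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  best <- list(loss = Inf, params = params, epoch = NA_integer_)
  t_adam <- 0L
  set.seed(cfg$seed)
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    for (start in seq(1L, n, by = cfg$batch_size)) {
      ix <- ord[start:min(start + cfg$batch_size - 1L, n)]
      imgs <- lapply(train$images[ix], function(im) {
        im <- augment(im, crop = cfg$crop, hflip = cfg$hflip,
                      vflip = cfg$vflip, stain = cfg$stain,
                      crop_size = size, stain_params = cfg$stain_params)
        if (any(dim(im)[1:2] != size)) im <- center_crop(im, size)
        im
      })
      mtmp <- model
      mtmp$params <- params
      fwd <- net_forward(mtmp, imgs, train = TRUE)
      yb <- y_all[ix, , drop = FALSE]
      ep_loss <- ep_loss + cross_entropy(yb, fwd$probs) * length(ix)
      grads <- net_backward(mtmp, fwd, yb)
      t_adam <- t_adam + 1L
      au <- adam_update(params, grads, state, cfg$learning_rate, t_adam)
      params <- au$params
      state <- au$state
    }
    mtmp <- model
    mtmp$params <- params
    vloss <- eval_loss(mtmp, val, cfg$batch_size)
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = ep_loss / n,
                                         val_loss = vloss))
    if (vloss < best$loss) best <- list(loss = vloss, params = params,
                                        epoch = epoch)
  }
  model$params <- best$params
  model$history <- history
  model$best_epoch <- best$epoch
  model
}
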