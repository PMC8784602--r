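# Grad-CAM regional interpretability. With a GAP + linear + softmax head the
# target-class probability is an explicit differentiable function of the
# last-pool feature tensor F, so the gradient G = dp_target/dF is available
# in closed form: for head logits z = W' GAP(F) + b and softmax p,
#   dp_t/dF[i,j,c] = sum_k p_t (1[k==t] - p_k) W[c,k] / (h*w),
# constant over spatial positions. The attention map is
# A = ReLU(F (x) w) with w the spatial GAP of G — the 1x1-convolution form
# of a channel-weighted sum.

#' Grad-CAM attention map for one ROI
#'
#' Computes the gradient of the target-class softmax probability with
#' respect to the last-pool feature tensor F, global-average-pools it into
#' a channel weight vector w, and returns `A = ReLU(F (x) w)` (h x w),
#' together with a bilinear upsampling of A to the network input size for
#' overlay rendering. The gradient is taken with respect to the
#' probability, not the logit.
#'
#' @param model a (typically trained) `"emb_cnn"`
#' @param image H x W x 3 array in \[0, 1\]
#' @param target class whose probability is differentiated:
#'   `"failure"` (default) or `"non_failure"`
#' @return an object of class `"emb_gradcam"`: `A` (h x w, nonnegative),
#'   `upsampled` (input_size^2), `w` (length C), `G` (h x w x C), the
#'   target and its predicted probability
#' @export
grad_cam <- function(model, image, target = c("failure", "non_failure")) {
  target <- match.arg(target)
  img <- prepare_input(model, image)
  fwd <- net_forward(model, list(img), train = FALSE)
  h <- fwd$h
  w_ <- fwd$w
  C <- ncol(fwd$fmat)
  p <- fwd$probs[1, ]
  tcol <- if (target == "failure") 2L else 1L
  # softmax jacobian row for the target node
  dp_dz <- p[tcol] * ((seq_len(2) == tcol) - p)
  Whead <- model$params$head$W
  g <- as.numeric(Whead %*% dp_dz) / (h * w_)
  G <- array(rep(g, each = h * w_), c(h, w_, C))
  wv <- g                                # spatial GAP of a constant field
  A <- matrix(pmax(fwd$fmat %*% wv, 0), h, w_)
  up <- bilinear_resize(A, model$spec$input_size, model$spec$input_size)
  structure(list(A = A, upsampled = up, w = wv, G = G, target = target,
                 probability = unname(p[tcol])),
            class = "emb_gradcam")
}

#' @export
print.emb_gradcam <- function(x, ...) {
  cat("Grad-CAM attention map (", nrow(x$A), "x", ncol(x$A), ") for target '",
      x$target, "' (p = ", format(x$probability, digits = 3), ")\n", sep = "")
  invisible(x)
}

#' Overlay an attention map on its source image
#'
#' Bilinearly upsamples the attention map to the image size, max-normalises
#' it (when its maximum is positive), maps it through a red (high) to green
#' (low) colormap, and alpha-blends it over the image.
#'
#' @param attention an `"emb_gradcam"` (or a bare nonnegative matrix)
#' @param image H x W x 3 array in \[0, 1\]
#' @param alpha blend weight of the heatmap (default 0.4)
#' @return blended H x W x 3 array
#' @export
overlay <- function(attention, image, alpha = 0.4) {
  A <- if (inherits(attention, "emb_gradcam")) attention$A else attention
  H <- dim(image)[1]
  W <- dim(image)[2]
  up <- bilinear_resize(A, H, W)
  mx <- max(up)
  if (mx > 0) up <- up / mx
  heat <- array(0, c(H, W, 3))
  heat[, , 1] <- up          # red = high attention
  heat[, , 2] <- 1 - up      # green = low attention
  clamp((1 - alpha) * image + alpha * heat, 0, 1)
}

#' Pairwise Euclidean distances between deep feature vectors
#'
#' @param features an n x C matrix (rows = ROIs) or a list of equal-length
#'   numeric vectors
#' @return symmetric n x n distance matrix with zero diagonal
#' @export
pairwise_distances <- function(features) {
  if (is.list(features) && !is.data.frame(features)) {
    len <- vapply(features, length, 0L)
    if (length(unique(len)) > 1) stop("feature vectors have unequal lengths")
    features <- do.call(rbind, features)
  }
  as.matrix(stats::dist(features))
}

#' 2-D UMAP embedding from a precomputed distance matrix
#'
#' Runs UMAP in precomputed-metric mode on the pairwise distance matrix of
#' deep features, producing one 2-D point per ROI. Deterministic given
#' `seed` (single-threaded layout optimisation).
#'
#' @param distances symmetric nonnegative n x n matrix, zero diagonal,
#'   n >= 10
#' @param seed integer seed
#' @param n_neighbors,min_dist UMAP hyperparameters (defaults 15 and 0.1;
#'   `n_neighbors` is clamped to n - 1)
#' @return data frame with columns `x`, `y`, one row per input ROI
#' @export
umap_embed <- function(distances, seed = 0L, n_neighbors = 15, min_dist = 0.1) {
  d <- as.matrix(distances)
  n <- nrow(d)
  if (n < 10) stop("need at least 10 samples to embed")
  if (ncol(d) != n || max(abs(d - t(d))) > 1e-8) {
    stop("distance matrix must be square and symmetric")
  }
  if (any(d < 0)) stop("distance matrix has negative entries")
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix diagonal must be zero")
  set.seed(seed)
  emb <- uwot::umap(stats::as.dist(d),
                    n_neighbors = min(n_neighbors, n - 1),
                    min_dist = min_dist, n_threads = 1, n_sgd_threads = 0)
  data.frame(x = emb[, 1], y = emb[, 2])
}

#' Scatter ROI thumbnails at their embedded coordinates
#'
#' Draws a random fraction of the ROI images as thumbnails at their 2-D
#' embedding coordinates (the remaining points are shown as dots).
#'
#' @param embedding data frame with `x`, `y` (from [umap_embed()])
#' @param images list of H x W x 3 arrays aligned with the embedding rows
#' @param sample_fraction fraction of ROIs drawn as thumbnails, in (0, 1\]
#' @param seed integer seed for the subsample
#' @param file optional PNG path; when given the figure is written there
#' @param thumb_frac thumbnail half-width as a fraction of the axis range
#' @return (invisibly) the integer indices of the sampled ROIs
#' @export
thumbnail_projection <- function(embedding, images, sample_fraction = 0.2,
                                 seed = 0L, file = NULL, thumb_frac = 0.03) {
  if (sample_fraction <= 0 || sample_fraction > 1) {
    stop("sample_fraction must be in (0, 1]")
  }
  n <- nrow(embedding)
  set.seed(seed)
  k <- max(1L, round(n * sample_fraction))
  sel <- sort(sample.int(n, k))
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 900)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  graphics::plot(embedding$x, embedding$y, pch = 16, cex = 0.3, col = "grey70",
                 xlab = "UMAP 1", ylab = "UMAP 2")
  rx <- diff(range(embedding$x)) * thumb_frac
  ry <- diff(range(embedding$y)) * thumb_frac
  for (i in sel) {
    im <- images[[i]]
    graphics::rasterImage(grDevices::as.raster(im),
                          embedding$x[i] - rx, embedding$y[i] - ry,
                          embedding$x[i] + rx, embedding$y[i] + ry)
  }
  invisible(sel)
}
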