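# Minimal CNN engine: 3x3 same-padding convolutions, ReLU, 2x2 max pooling,
# global average pooling and a linear softmax head, with exact backprop.
#
# Activations are stored as (H*W*N) x C matrices, rows ordered h fastest,
# then w, then image index n (so each image's block reshapes directly into an
# (h, w) R array). Convolutions are evaluated as im2col gathers followed by a
# single GEMM, which is what makes CPU training viable: all heavy lifting is
# delegated to BLAS.

.idx_cache <- new.env(parent = emptyenv())

# 3x3 same-padding gather indices into a zero-padded (H+2) x (W+2) plane,
# expanded across N images. Cached per (H, W, N).
conv_indices <- function(H, W, N) {
  key <- paste0("c", H, "_", W, "_", N)
  got <- .idx_cache[[key]]
  if (!is.null(got)) return(got)
  Hp <- H + 2L
  Wp <- W + 2L
  h <- rep(seq_len(H), times = W)
  w <- rep(seq_len(W), each = H)
  off <- (seq_len(N) - 1L) * Hp * Wp
  expand <- function(idx) rep(idx, times = N) + rep(off, each = length(idx))
  idx <- vector("list", 9L)
  k <- 0L
  for (dw in -1:1) {
    for (dh in -1:1) {
      k <- k + 1L
      idx[[k]] <- expand((h + 1L + dh) + (w + dw) * Hp)
    }
  }
  out <- list(idx = idx, interior = expand((h + 1L) + w * Hp), Hp = Hp, Wp = Wp)
  .idx_cache[[key]] <- out
  out
}

# 2x2 stride-2 pooling indices; a trailing odd row/column is dropped
# (floor semantics), so the output side is floor(side / 2).
pool_indices <- function(H, W, N) {
  key <- paste0("p", H, "_", W, "_", N)
  got <- .idx_cache[[key]]
  if (!is.null(got)) return(got)
  Ho <- H %/% 2L
  Wo <- W %/% 2L
  h <- rep(seq_len(Ho), times = Wo)
  w <- rep(seq_len(Wo), each = Ho)
  off <- (seq_len(N) - 1L) * H * W
  expand <- function(idx) rep(idx, times = N) + rep(off, each = length(idx))
  idx <- vector("list", 4L)
  k <- 0L
  for (dw in 0:1) {
    for (dh in 0:1) {
      k <- k + 1L
      idx[[k]] <- expand((2L * h - 1L + dh) + (2L * w - 2L + dw) * H)
    }
  }
  out <- list(idx = idx, Ho = Ho, Wo = Wo)
  .idx_cache[[key]] <- out
  out
}

# Same-padding 3x3 convolution evaluated as 9 shifted GEMMs against the
# zero-padded activation (never materialising the full im2col matrix keeps
# memory traffic low, which dominates run time for narrow layers).
conv_fwd <- function(x, H, W, N, Wmat, b, keep = FALSE) {
  C <- ncol(x)
  ci <- conv_indices(H, W, N)
  Xp <- matrix(0, ci$Hp * ci$Wp * N, C)
  Xp[ci$interior, ] <- x
  y <- NULL
  for (o in 1:9) {
    blk <- Wmat[((o - 1L) * C + 1L):(o * C), , drop = FALSE]
    contrib <- Xp[ci$idx[[o]], , drop = FALSE] %*% blk
    y <- if (is.null(y)) contrib else y + contrib
  }
  y <- y + rep(b, each = nrow(y))
  list(y = y, xp = if (keep) Xp)
}

conv_bwd <- function(dY, Xp, Wmat, H, W, N, want_dx = TRUE) {
  Cin <- nrow(Wmat) %/% 9L
  ci <- conv_indices(H, W, N)
  dW <- matrix(0, nrow(Wmat), ncol(Wmat))
  db <- colSums(dY)
  dXp <- if (want_dx) matrix(0, ci$Hp * ci$Wp * N, Cin)
  for (o in 1:9) {
    rows <- ((o - 1L) * Cin + 1L):(o * Cin)
    ix <- ci$idx[[o]]
    dW[rows, ] <- crossprod(Xp[ix, , drop = FALSE], dY)
    if (want_dx) {
      dXp[ix, ] <- dXp[ix, , drop = FALSE] +
        tcrossprod(dY, Wmat[rows, , drop = FALSE])
    }
  }
  list(dX = if (want_dx) dXp[ci$interior, , drop = FALSE], dW = dW, db = db)
}

pool_fwd <- function(x, H, W, N, keep = FALSE) {
  pidx <- pool_indices(H, W, N)
  best <- x[pidx$idx[[1]], , drop = FALSE]
  amax <- matrix(1L, nrow(best), ncol(best))
  for (k in 2:4) {
    cand <- x[pidx$idx[[k]], , drop = FALSE]
    m <- cand > best
    best[m] <- cand[m]
    amax[m] <- k
  }
  list(y = best, amax = if (keep) amax, Ho = pidx$Ho, Wo = pidx$Wo)
}

pool_bwd <- function(dY, amax, H, W, N, C) {
  pidx <- pool_indices(H, W, N)
  HWN <- H * W * N
  nout <- nrow(dY)
  dX <- matrix(0, HWN, C)
  for (k in 1:4) {
    p <- which(amax == k)
    if (!length(p)) next
    row <- ((p - 1L) %% nout) + 1L
    col <- (p - 1L) %/% nout
    tgt <- pidx$idx[[k]][row] + col * HWN
    dX[tgt] <- dX[tgt] + dY[p]
  }
  dX
}

gap_fwd <- function(x, H, W, N) {
  out <- rowsum(x, group = rep(seq_len(N), each = H * W), reorder = FALSE) /
    (H * W)
  rownames(out) <- NULL
  out
}

gap_bwd <- function(dY, H, W, N) {
  dY[rep(seq_len(N), each = H * W), , drop = FALSE] / (H * W)
}

# Row-wise softmax over an N x K logit matrix, numerically stabilised.
softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Stack a list of H x W x 3 image arrays into the engine's (H*W*N) x 3
# activation layout, centring pixel values at zero.
stack_images <- function(imgs) {
  H <- dim(imgs[[1]])[1]
  W <- dim(imgs[[1]])[2]
  N <- length(imgs)
  x <- matrix(0, H * W * N, 3L)
  for (n in seq_len(N)) {
    im <- imgs[[n]]
    if (length(dim(im)) != 3 || dim(im)[3] != 3) {
      stop("expected an H x W x 3 RGB array, got dims ",
           paste(dim(im), collapse = "x"))
    }
    x[((n - 1L) * H * W) + seq_len(H * W), ] <- matrix(im, H * W, 3L)
  }
  list(x = x - 0.5, H = H, W = W, N = N)
}

# He-scaled Gaussian initialisation for one conv layer.
init_conv <- function(cin, cout) {
  list(W = matrix(stats::rnorm(9L * cin * cout, sd = sqrt(2 / (9 * cin))),
                  9L * cin, cout),
       b = numeric(cout))
}

# Full forward pass. Returns probabilities, the last-pool feature tensor F
# (as an (h*w*N) x C matrix), GAP deep features, logits, and (when
# `train = TRUE`) every cache needed for the backward pass.
net_forward <- function(model, imgs, train = FALSE) {
  sp <- model$spec
  st <- stack_images(imgs)
  x <- st$x
  H <- st$H
  W <- st$W
  N <- st$N
  caches <- if (train) list(conv = list(), pool = list())
  l <- 0L
  for (s in seq_len(sp$n_pool_stages)) {
    for (j in seq_len(sp$convs_per_stage[s])) {
      l <- l + 1L
      pr <- model$params$conv[[l]]
      cf <- conv_fwd(x, H, W, N, pr$W, pr$b, keep = train)
      y <- cf$y
      mask <- y > 0
      x <- y * mask
      if (train) caches$conv[[l]] <- list(xp = cf$xp, mask = mask, H = H, W = W)
    }
    pf <- pool_fwd(x, H, W, N, keep = train)
    x <- pf$y
    if (train) caches$pool[[s]] <- list(amax = pf$amax, H = H, W = W)
    H <- pf$Ho
    W <- pf$Wo
    if (H < 1L || W < 1L) stop("input too small for ", sp$n_pool_stages, " pooling stages")
  }
  fmat <- x
  deep <- gap_fwd(fmat, H, W, N)
  logits <- deep %*% model$params$head$W + rep(model$params$head$b, each = N)
  probs <- softmax_rows(logits)
  list(probs = probs, fmat = fmat, deep = deep, logits = logits,
       h = H, w = W, N = N, caches = caches)
}

# Backward pass from softmax + (1/|C|)-normalised cross-entropy.
# Returns gradients in the same structure as model$params.
net_backward <- function(model, fwd, y_onehot) {
  sp <- model$spec
  N <- fwd$N
  # d loss / d logits for L = mean_n (1/2) * sum_c -y_c log p_c
  dz <- 0.5 * (fwd$probs - y_onehot) / N
  g_head_W <- crossprod(fwd$deep, dz)
  g_head_b <- colSums(dz)
  dDeep <- tcrossprod(dz, model$params$head$W)
  h <- fwd$h
  w <- fwd$w
  dx <- gap_bwd(dDeep, h, w, N)
  g_conv <- vector("list", length(model$params$conv))
  l <- length(model$params$conv)
  for (s in rev(seq_len(sp$n_pool_stages))) {
    pc <- fwd$caches$pool[[s]]
    dx <- pool_bwd(dx, pc$amax, pc$H, pc$W, N, ncol(dx))
    for (j in rev(seq_len(sp$convs_per_stage[s]))) {
      cc <- fwd$caches$conv[[l]]
      dx <- dx * cc$mask
      bw <- conv_bwd(dx, cc$xp, model$params$conv[[l]]$W, cc$H, cc$W, N,
                     want_dx = l > 1L)
      g_conv[[l]] <- list(W = bw$dW, b = bw$db)
      dx <- bw$dX
      l <- l - 1L
    }
  }
  list(conv = g_conv, head = list(W = g_head_W, b = g_head_b))
}

# One Adam update over the whole parameter tree (in place on copies).
adam_update <- function(params, grads, state, lr, t,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  upd <- function(p, g, st) {
    st$m <- beta1 * st$m + (1 - beta1) * g
    st$v <- beta2 * st$v + (1 - beta2) * g * g
    mhat <- st$m / (1 - beta1^t)
    vhat <- st$v / (1 - beta2^t)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), st = st)
  }
  for (l in seq_along(params$conv)) {
    for (nm in c("W", "b")) {
      r <- upd(params$conv[[l]][[nm]], grads$conv[[l]][[nm]], state$conv[[l]][[nm]])
      params$conv[[l]][[nm]] <- r$p
      state$conv[[l]][[nm]] <- r$st
    }
  }
  for (nm in c("W", "b")) {
    r <- upd(params$head[[nm]], grads$head[[nm]], state$head[[nm]])
    params$head[[nm]] <- r$p
    state$head[[nm]] <- r$st
  }
  list(params = params, state = state)
}

adam_init <- function(params) {
  zero <- function(p) list(m = p * 0, v = p * 0)
  list(conv = lapply(params$conv, function(l) list(W = zero(l$W), b = zero(l$b))),
       head = list(W = zero(params$head$W), b = zero(params$head$b)))
}
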