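# Internal helpers shared across modules.

#' Deterministically mix integers into a single 31-bit seed
#'
#' Used to derive independent sub-seeds (per case, per ROI, per sub-model)
#' from a master seed, so any element of a run is regenerable in isolation.
#' Splitmix-style multiply/xor mixing, reduced mod 2^31 - 1 to stay within
#' R's integer range.
#'
#' @param ... integers to mix (order matters)
#' @return a single integer in [0, 2^31 - 2]
#' @keywords internal
mix_seed <- function(...) {
  xs <- c(...)
  # multiplier kept small enough that acc * mult stays exact in a double
  acc <- 17
  for (x in xs) {
    acc <- (acc * 48271 + (as.double(x) %% 2147483647) + 11) %% 2147483647
    acc <- (acc * 48271 + 7919) %% 2147483647
  }
  as.integer(acc)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Bilinear resize of a matrix
#'
#' Resamples a numeric matrix to a new size using bilinear interpolation with
#' half-pixel-centred coordinates (the convention used when upsampling an
#' attention map onto the image it was computed from).
#'
#' @param m numeric matrix
#' @param nrow_out,ncol_out output dimensions
#' @return numeric matrix `nrow_out` x `ncol_out`
#' @keywords internal
bilinear_resize <- function(m, nrow_out, ncol_out) {
  H <- nrow(m); W <- ncol(m)
  if (H == nrow_out && W == ncol_out) return(m)
  # half-pixel centres: output pixel i maps to (i - 0.5) * H / Hout + 0.5
  yi <- (seq_len(nrow_out) - 0.5) * H / nrow_out + 0.5
  xi <- (seq_len(ncol_out) - 0.5) * W / ncol_out + 0.5
  y0 <- clamp(floor(yi), 1, H); y1 <- clamp(y0 + 1, 1, H)
  x0 <- clamp(floor(xi), 1, W); x1 <- clamp(x0 + 1, 1, W)
  fy <- clamp(yi - y0, 0, 1); fx <- clamp(xi - x0, 0, 1)
  a <- m[y0, x0, drop = FALSE] * (1 - fy) + m[y1, x0, drop = FALSE] * fy
  b <- m[y0, x1, drop = FALSE] * (1 - fy) + m[y1, x1, drop = FALSE] * fy
  a * rep(1 - fx, each = nrow_out) + b * rep(fx, each = nrow_out)
}

# Resize an H x W x C array channel by channel.
bilinear_resize_rgb <- function(img, nrow_out, ncol_out) {
  out <- array(0, c(nrow_out, ncol_out, dim(img)[3]))
  for (c in seq_len(dim(img)[3])) {
    out[, , c] <- bilinear_resize(img[, , c], nrow_out, ncol_out)
  }
  out
}

# Centred square crop of an H x W x C image array.
center_crop <- function(img, size) {
  H <- dim(img)[1]; W <- dim(img)[2]
  if (H < size || W < size) {
    stop("image (", H, "x", W, ") smaller than crop size ", size)
  }
  r0 <- (H - size) %/% 2L
  c0 <- (W - size) %/% 2L
  img[r0 + seq_len(size), c0 + seq_len(size), , drop = FALSE]
}

# Validate a label vector against the two-class vocabulary.
check_labels <- function(labels) {
  bad <- setdiff(unique(labels), c("failure", "non_failure"))
  if (length(bad)) {
    stop("unknown label(s): ", paste(bad, collapse = ", "),
         " (expected 'failure' or 'non_failure')")
  }
  invisible(labels)
}
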