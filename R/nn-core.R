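#' Elementwise rectified linear unit
#'
#' `relu(x) = max(0, x)`, applied elementwise to any numeric array.
#'
#' @param x Numeric vector or array.
#' @return Object of the same shape with negative entries clamped to zero.
#' @export
relu <- function(x) {
  pmax(x, 0)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Batch normalization
#'
#' Per-channel affine standardization
#' `BN(x) = gamma * (x - mu) / sqrt(sigma2 + eps) + beta`. The moments
#' `mu`/`sigma2` are taken as given (inference-style normalization); when
#' `NULL` they are computed from `x` itself over the spatial (and batch)
#' dimensions.
#'
#' @param x An H x W x C feature map or a list of them (a batch).
#' @param gamma,beta Per-channel scale and shift (length C or scalar).
#' @param mu,sigma2 Per-channel mean and variance; computed from the input
#'   when `NULL`. `sigma2` uses the population (1/N) convention.
#' @param eps Small positive constant guarding a zero variance.
#' @return Normalized map(s), same shape as `x`.
#' @export
batch_norm <- function(x, gamma = 1, beta = 0, mu = NULL, sigma2 = NULL,
                       eps = 1e-5) {
  assert_that(eps > 0, "eps must be > 0")
  batched <- is.list(x)
  maps <- if (batched) lapply(x, as_fmap) else list(as_fmap(x))
  C <- fmap_c(maps[[1L]])
  if (is.null(mu) || is.null(sigma2)) {
    per_ch <- vapply(seq_len(C), function(c) {
      v <- unlist(lapply(maps, function(m) m[, , c]), use.names = FALSE)
      c(mean(v), mean((v - mean(v))^2))
    }, numeric(2))
    if (is.null(mu)) mu <- per_ch[1L, ]
    if (is.null(sigma2)) sigma2 <- per_ch[2L, ]
  }
  assert_that(all(sigma2 >= 0), "sigma2 must be nonnegative")
  gamma <- rep_len(gamma, C); beta <- rep_len(beta, C)
  mu <- rep_len(mu, C); sigma2 <- rep_len(sigma2, C)
  out <- lapply(maps, function(m) {
    for (c in seq_len(C)) {
      m[, , c] <- gamma[c] * (m[, , c] - mu[c]) / sqrt(sigma2[c] + eps) +
        beta[c]
    }
    m
  })
  if (batched) out else out[[1L]]
}

# Zero-pad an H x W x C array spatially.
pad_fmap <- function(x, pad_h, pad_w = pad_h) {
  if (pad_h == 0 && pad_w == 0) return(x)
  d <- dim(x)
  out <- array(0, c(d[1L] + 2 * pad_h, d[2L] + 2 * pad_w, d[3L]))
  out[pad_h + seq_len(d[1L]), pad_w + seq_len(d[2L]), ] <- x
  out
}

# im2col: unfold kh x kw patches into a (Ho*Wo) x (kh*kw*C) matrix.
# Column blocks are ordered (ky, kx) with kx fastest, channels fastest
# within a block; conv2d's weight flattening matches this order.
im2col <- function(xp, kh, kw, stride, ho, wo) {
  C <- dim(xp)[3L]
  cols <- matrix(0, ho * wo, kh * kw * C)
  ys0 <- seq.int(1L, by = stride, length.out = ho)
  xs0 <- seq.int(1L, by = stride, length.out = wo)
  b <- 0L
  for (ky in seq_len(kh)) {
    for (kx in seq_len(kw)) {
      b <- b + 1L
      block <- xp[ys0 + (ky - 1L), xs0 + (kx - 1L), , drop = FALSE]
      cols[, ((b - 1L) * C + 1L):(b * C)] <- matrix(block, ho * wo, C)
    }
  }
  cols
}

#' 2-d convolution
#'
#' Cross-correlation of an H x W x C map with a bank of kernels, the
#' convolution primitive used by every block in the package. Implemented as
#' im2col + matrix multiply.
#'
#' @param x H x W x C array.
#' @param w Kernel array kh x kw x C_in x C_out.
#' @param b Bias vector (length C_out) or `NULL`.
#' @param stride Positive integer stride.
#' @param pad `"same"` (zero padding preserving ceiling(H/stride)) or a
#'   nonnegative integer pad width.
#' @return Ho x Wo x C_out array.
#' @export
conv2d <- function(x, w, b = NULL, stride = 1L, pad = "same") {
  x <- as_fmap(x)
  assert_that(length(dim(w)) == 4L, "w must be kh x kw x C_in x C_out")
  kh <- dim(w)[1L]; kw <- dim(w)[2L]
  assert_that(dim(w)[3L] == fmap_c(x),
              "kernel input channels must match the feature map")
  if (identical(pad, "same")) {
    pad_h <- (kh - 1L) %/% 2L
    pad_w <- (kw - 1L) %/% 2L
  } else {
    pad_h <- pad_w <- as.integer(pad)
  }
  xp <- pad_fmap(x, pad_h, pad_w)
  ho <- (dim(xp)[1L] - kh) %/% stride + 1L
  wo <- (dim(xp)[2L] - kw) %/% stride + 1L
  cols <- im2col(xp, kh, kw, stride, ho, wo)
  wm <- matrix(aperm(w, c(3L, 2L, 1L, 4L)), ncol = dim(w)[4L])
  out <- cols %*% wm
  if (!is.null(b)) out <- sweep(out, 2L, rep_len(b, ncol(out)), "+")
  array(out, c(ho, wo, dim(w)[4L]))
}

#' Max pooling
#'
#' @param x H x W x C array.
#' @param k Pooling window size.
#' @param stride Stride (defaults to `k`).
#' @param pad Zero-padding width (padding uses -Inf so it never wins).
#' @return Pooled array.
#' @export
max_pool <- function(x, k = 2L, stride = k, pad = 0L) {
  x <- as_fmap(x)
  d <- dim(x)
  if (pad > 0) {
    xp <- array(-Inf, c(d[1L] + 2L * pad, d[2L] + 2L * pad, d[3L]))
    xp[pad + seq_len(d[1L]), pad + seq_len(d[2L]), ] <- x
  } else {
    xp <- x
  }
  ho <- (dim(xp)[1L] - k) %/% stride + 1L
  wo <- (dim(xp)[2L] - k) %/% stride + 1L
  ys0 <- seq.int(1L, by = stride, length.out = ho)
  xs0 <- seq.int(1L, by = stride, length.out = wo)
  out <- array(-Inf, c(ho, wo, d[3L]))
  for (ky in seq_len(k)) {
    for (kx in seq_len(k)) {
      out <- pmax(out, xp[ys0 + (ky - 1L), xs0 + (kx - 1L), , drop = FALSE])
    }
  }
  out
}

#' Adaptive average pooling
#'
#' Averages each channel over integer bins chosen so the output has exactly
#' `out_h x out_w` cells; bin `i` covers rows `floor((i-1)*H/out_h)+1` to
#' `ceiling(i*H/out_h)`. Deterministic downscaling used inside the balanced
#' pyramid's Integrate step.
#'
#' @param x H x W x C array.
#' @param out_h,out_w Output spatial dims.
#' @return out_h x out_w x C array.
#' @export
adaptive_avg_pool <- function(x, out_h, out_w) {
  x <- as_fmap(x)
  d <- dim(x)
  ylo <- floor((seq_len(out_h) - 1) * d[1L] / out_h) + 1L
  yhi <- ceiling(seq_len(out_h) * d[1L] / out_h)
  xlo <- floor((seq_len(out_w) - 1) * d[2L] / out_w) + 1L
  xhi <- ceiling(seq_len(out_w) * d[2L] / out_w)
  out <- array(0, c(out_h, out_w, d[3L]))
  for (i in seq_len(out_h)) {
    for (j in seq_len(out_w)) {
      block <- x[ylo[i]:yhi[i], xlo[j]:xhi[j], , drop = FALSE]
      out[i, j, ] <- colMeans(matrix(block, ncol = d[3L]))
    }
  }
  out
}

# Vectorized bilinear sampling of one channel (matrix `m`) at continuous
# 0-based coordinates (ys, xs). Out-of-range samples read as 0 (zero pad).
bilinear_gather <- function(m, ys, xs) {
  h <- nrow(m); w <- ncol(m)
  y0 <- floor(ys); x0 <- floor(xs)
  dy <- ys - y0; dx <- xs - x0
  val <- function(yy, xx) {
    ok <- yy >= 0 & yy <= h - 1 & xx >= 0 & xx <= w - 1
    out <- numeric(length(yy))
    if (any(ok)) out[ok] <- m[cbind(yy[ok] + 1, xx[ok] + 1)]
    out
  }
  val(y0, x0) * (1 - dy) * (1 - dx) +
    val(y0, x0 + 1) * (1 - dy) * dx +
    val(y0 + 1, x0) * dy * (1 - dx) +
    val(y0 + 1, x0 + 1) * dy * dx
}

#' Bilinear resize
#'
#' Resamples an H x W x C array to a target size with the half-pixel-center
#' convention (`src = (dst + 0.5) * scale - 0.5`). Resizing to the input size
#' reproduces the input exactly.
#'
#' @param x H x W x C array (or matrix).
#' @param out_h,out_w Target spatial dims.
#' @return Resized array.
#' @export
bilinear_resize <- function(x, out_h, out_w) {
  x <- as_fmap(x)
  d <- dim(x)
  if (out_h == d[1L] && out_w == d[2L]) return(x)
  sy <- d[1L] / out_h
  sx <- d[2L] / out_w
  ys <- pmin(pmax((seq_len(out_h) - 0.5) * sy - 0.5, 0), d[1L] - 1)
  xs <- pmin(pmax((seq_len(out_w) - 0.5) * sx - 0.5, 0), d[2L] - 1)
  grid_y <- rep(ys, times = out_w)
  grid_x <- rep(xs, each = out_h)
  out <- array(0, c(out_h, out_w, d[3L]))
  for (c in seq_len(d[3L])) {
    out[, , c] <- matrix(bilinear_gather(x[, , c], grid_y, grid_x),
                         out_h, out_w)
  }
  out
}

# Nearest-neighbour integer-factor upsampling (each pixel repeated s times).
nearest_upsample <- function(x, s = 2L) {
  x <- as_fmap(x)
  d <- dim(x)
  x[rep(seq_len(d[1L]), each = s), rep(seq_len(d[2L]), each = s), ,
    drop = FALSE]
}

# Numerically stable softmax along a vector.
softmax_vec <- function(v) {
  e <- exp(v - max(v))
  e / sum(e)
}

# Stable softmax over the 3rd dim of an H x W x K array, per location.
softmax_channels <- function(x) {
  mx <- apply(x, c(1L, 2L), max)
  e <- exp(x - as.vector(mx))
  s <- apply(e, c(1L, 2L), sum)
  e / as.vector(s)
}

# He-style Gaussian initialization for a conv kernel, seeded.
init_conv <- function(kh, kw, c_in, c_out, seed, gain = 1) {
  n <- kh * kw * c_in * c_out
  sd <- gain * sqrt(2 / (kh * kw * c_in))
  with_seed(seed, array(rnorm(n, 0, sd), c(kh, kw, c_in, c_out)))
}

init_mat <- function(nin, nout, seed, gain = 1) {
  with_seed(seed, matrix(rnorm(nin * nout, 0, gain * sqrt(2 / nin)),
                         nin, nout))
}
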