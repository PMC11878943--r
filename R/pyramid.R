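#' CARAFE hyperparameters
#'
#' @param k_up Reassembly kernel size (odd; 5).
#' @param k_enc Kernel-prediction encoder size (3).
#' @param c_mid Compressed channel width fed to the encoder (64).
#' @param sigma Integer upsampling ratio (2).
#' @return List of class `carafe_params`.
#' @export
carafe_params <- function(k_up = 5L, k_enc = 3L, c_mid = 64L, sigma = 2L) {
  if (k_up %% 2L != 1L) {
    abort("k_up must be odd", class = "foalwatch_config_error")
  }
  assert_that(is_count(sigma, 1L), "sigma must be a count >= 1")
  structure(list(k_up = as.integer(k_up), k_enc = as.integer(k_enc),
                 c_mid = as.integer(c_mid), sigma = as.integer(sigma)),
            class = "carafe_params")
}

#' CARAFE weights
#'
#' The content encoder: a 1x1 channel compressor to `c_mid` and a
#' `k_enc x k_enc` convolution predicting `k_up^2 * sigma^2` kernel logits
#' per source location.
#'
#' @param c_in Input channel width.
#' @param params [carafe_params()].
#' @param seed Integer seed.
#' @return List with `w_compress`, `w_enc`.
#' @export
carafe_weights <- function(c_in, params = carafe_params(), seed = 1L) {
  list(
    w_compress = init_conv(1L, 1L, c_in, params$c_mid, child_seed(seed, 1)),
    w_enc = init_conv(params$k_enc, params$k_enc, params$c_mid,
                      params$k_up^2 * params$sigma^2, child_seed(seed, 2))
  )
}

# Predict per-output-location reassembly kernels: (sigma*H) x (sigma*W) x
# k_up^2, softmax-normalized (with max subtraction) at every location.
carafe_predict_kernels <- function(x, params, weights) {
  logits <- conv2d(conv2d(x, weights$w_compress, pad = 0L), weights$w_enc,
                   pad = "same")
  h <- dim(logits)[1L]; w <- dim(logits)[2L]
  s <- params$sigma; k2 <- params$k_up^2
  up <- array(0, c(h * s, w * s, k2))
  for (dy in seq_len(s)) {
    for (dx in seq_len(s)) {
      ch0 <- ((dy - 1L) * s + (dx - 1L)) * k2
      up[seq.int(dy, by = s, length.out = h),
         seq.int(dx, by = s, length.out = w), ] <-
        logits[, , ch0 + seq_len(k2), drop = FALSE]
    }
  }
  softmax_channels(up)
}

#' Reassemble features under given CARAFE kernels
#'
#' Applies per-output-location kernels `alpha` over the `k_up x k_up`
#' zero-padded source neighbourhood of each output pixel:
#' `y[i, j] = sum_{m,n} alpha[i, j, m, n] * x[m, n]`. Exposed separately so
#' forced kernels (uniform, one-hot) can be checked against closed forms.
#'
#' @param x H x W x C source map.
#' @param alpha (sigma H) x (sigma W) x k_up^2 kernel array; the third axis
#'   enumerates the neighbourhood row-major (ky, kx) with kx fastest.
#' @param params [carafe_params()].
#' @param renormalize Renormalize each kernel over its in-bounds taps, so
#'   kernel mass never falls on the zero padding outside the source (this
#'   is what makes constants exact fixed points of the predicted-kernel
#'   operator). `FALSE` by default: forced kernels are applied exactly as
#'   given over the zero-padded neighbourhood.
#' @return (sigma H) x (sigma W) x C array.
#' @export
carafe_apply_kernels <- function(x, alpha, params = carafe_params(),
                                 renormalize = FALSE) {
  x <- as_fmap(x)
  s <- params$sigma; k <- params$k_up
  d <- dim(x)
  oh <- d[1L] * s; ow <- d[2L] * s
  assert_that(all(dim(alpha)[1:2] == c(oh, ow)) && dim(alpha)[3L] == k^2,
              "alpha dims do not match the output grid")
  pad <- (k - 1L) %/% 2L
  xp <- pad_fmap(x, pad)
  base_y <- (seq_len(oh) - 1L) %/% s + 1L  # source row per output row
  base_x <- (seq_len(ow) - 1L) %/% s + 1L
  tap_valid <- function(ky, kx) {
    vy <- base_y + ky - 1L - pad
    vx <- base_x + kx - 1L - pad
    outer(vy >= 1L & vy <= d[1L], vx >= 1L & vx <= d[2L])
  }
  if (renormalize) {
    # restrict each kernel to its in-bounds taps; if a saturated kernel
    # put all of its mass out of bounds, fall back to a uniform kernel
    # over the valid taps
    wsum <- matrix(0, oh, ow)
    nvalid <- matrix(0, oh, ow)
    j <- 0L
    for (ky in seq_len(k)) {
      for (kx in seq_len(k)) {
        j <- j + 1L
        v <- tap_valid(ky, kx)
        wsum <- wsum + alpha[, , j] * v
        nvalid <- nvalid + v
      }
    }
    degenerate <- wsum < 1e-12
  }
  out <- array(0, c(oh, ow, d[3L]))
  j <- 0L
  for (ky in seq_len(k)) {
    for (kx in seq_len(k)) {
      j <- j + 1L
      slab <- xp[base_y + (ky - 1L), base_x + (kx - 1L), , drop = FALSE]
      a_j <- alpha[, , j]
      if (renormalize) {
        v <- tap_valid(ky, kx)
        a_j <- ifelse(degenerate, v / nvalid,
                      a_j * v / pmax(wsum, 1e-12))
      }
      out <- out + slab * as.vector(a_j)
    }
  }
  out
}

#' Content-aware reassembly upsampling (CARAFE)
#'
#' Predicts a softmax-normalized `k_up x k_up` kernel for every output
#' location from the channel-compressed content, then reassembles the
#' source neighbourhood under those kernels. Because every kernel sums to
#' one, constant inputs are fixed points (up to the ratio change in size).
#'
#' @param x H x W x C source map.
#' @param params [carafe_params()].
#' @param weights [carafe_weights()]; required unless `kernels` is given.
#' @param kernels Optional pre-computed kernels (see
#'   [carafe_apply_kernels()]); overrides prediction.
#' @return (sigma H) x (sigma W) x C array.
#' @export
carafe_upsample <- function(x, params = carafe_params(), weights = NULL,
                            kernels = NULL) {
  x <- as_fmap(x)
  forced <- !is.null(kernels)
  if (!forced) {
    assert_that(!is.null(weights), "weights are required to predict kernels")
    kernels <- carafe_predict_kernels(x, params, weights)
  }
  # predicted kernels are renormalized over in-bounds taps so that border
  # locations do not leak mass onto the padding (constants stay exact
  # fixed points); forced kernels are honoured verbatim
  carafe_apply_kernels(x, kernels, params, renormalize = !forced)
}

# --- feature pyramid ---------------------------------------------------

new_pyramid <- function(levels, strides) {
  structure(list(levels = levels, strides = strides),
            class = "feature_pyramid")
}

#' @export
print.feature_pyramid <- function(x, ...) {
  cat("<feature_pyramid>\n")
  for (nm in names(x$levels)) {
    d <- dim(x$levels[[nm]])
    cat(sprintf("  %s: %d x %d x %d (stride %d)\n", nm, d[1], d[2], d[3],
                x$strides[[nm]]))
  }
  invisible(x)
}

#' Weights for the top-down pyramid
#'
#' @param in_channels Named/ordered channel widths of C2..C5.
#' @param out_channels Common width after lateral projection.
#' @param params [carafe_params()] used when the CARAFE upsampler is chosen.
#' @param seed Integer seed.
#' @return List with lateral 1x1 kernels and per-step CARAFE weights.
#' @export
fpn_weights <- function(in_channels, out_channels = 32L,
                        params = carafe_params(), seed = 1L) {
  laterals <- lapply(seq_along(in_channels), function(i) {
    init_conv(1L, 1L, in_channels[i], out_channels, child_seed(seed, i))
  })
  carafe <- lapply(1:3, function(i) {
    carafe_weights(out_channels, params, child_seed(seed, 100L + i))
  })
  list(laterals = laterals, carafe = carafe, out_channels = out_channels)
}

resize_nearest <- function(x, oh, ow) {
  x <- as_fmap(x)
  d <- dim(x)
  yi <- pmin(d[1L], floor((seq_len(oh) - 0.5) * d[1L] / oh) + 1L)
  xi <- pmin(d[2L], floor((seq_len(ow) - 0.5) * d[2L] / ow) + 1L)
  x[yi, xi, , drop = FALSE]
}

#' Top-down feature pyramid (P2'..P6')
#'
#' Lateral 1x1 projections of C2..C5 to a common width, top-down fusion in
#' which each coarser level is upsampled (CARAFE by default, nearest
#' otherwise) and added to the next lateral, plus a stride-2 pooled P6'.
#'
#' @param cmaps Named list `C2..C5` from [backbone_forward()].
#' @param weights [fpn_weights()].
#' @param upsampler `"carafe"` or `"nearest"`.
#' @param params [carafe_params()].
#' @return A `feature_pyramid` with levels `P2..P6` (the pre-balance P').
#' @export
fpn_topdown <- function(cmaps, weights, upsampler = c("carafe", "nearest"),
                        params = carafe_params()) {
  upsampler <- match.arg(upsampler)
  assert_that(length(cmaps) == 4L, "expected the 4 levels C2..C5")
  lat <- lapply(1:4, function(i) {
    conv2d(as_fmap(cmaps[[i]]), weights$laterals[[i]], pad = 0L)
  })
  ps <- vector("list", 4L)
  ps[[4L]] <- lat[[4L]]
  for (i in 3:1) {
    coarse <- ps[[i + 1L]]
    target <- dim(lat[[i]])
    up <- if (upsampler == "carafe") {
      carafe_upsample(coarse, params, weights$carafe[[4L - i]])
    } else {
      nearest_upsample(coarse, 2L)
    }
    up <- up[seq_len(target[1L]), seq_len(target[2L]), , drop = FALSE]
    ps[[i]] <- lat[[i]] + up
  }
  p6 <- max_pool(ps[[4L]], k = 1L, stride = 2L)
  levels <- c(ps, list(p6))
  names(levels) <- paste0("P", 2:6)
  new_pyramid(levels, setNames(c(4L, 8L, 16L, 32L, 64L), paste0("P", 2:6)))
}

#' Integrate pyramid levels to a reference resolution
#'
#' Resizes P2'..P5' to the reference level's spatial dims (adaptive average
#' pooling down, nearest-neighbour up by default) and averages them into a
#' single balanced map.
#'
#' @param pyramid A `feature_pyramid` (only levels P2..P5 are merged).
#' @param reference Level name used as the target resolution (`"P4"`).
#' @param upsampler `"nearest"` or `"bilinear"` for levels coarser than the
#'   reference.
#' @return Feature map at the reference level's dims.
#' @export
bfp_integrate <- function(pyramid, reference = "P4",
                          upsampler = c("nearest", "bilinear")) {
  upsampler <- match.arg(upsampler)
  use <- intersect(paste0("P", 2:5), names(pyramid$levels))
  assert_that(length(use) >= 2L, "need at least 2 levels to integrate")
  ref <- dim(pyramid$levels[[reference]])
  resized <- lapply(use, function(nm) {
    m <- pyramid$levels[[nm]]
    d <- dim(m)
    if (d[1L] == ref[1L] && d[2L] == ref[2L]) return(m)
    if (d[1L] >= ref[1L]) {
      adaptive_avg_pool(m, ref[1L], ref[2L])
    } else if (upsampler == "nearest") {
      resize_nearest(m, ref[1L], ref[2L])
    } else {
      bilinear_resize(m, ref[1L], ref[2L])
    }
  })
  Reduce(`+`, resized) / length(resized)
}

#' Refine a balanced feature map
#'
#' Residual refinement `x + T(x)`; `T` is a 3x3 convolution by default or
#' an embedded-Gaussian non-local block. With zero weights the refinement
#' is the identity.
#'
#' @param x Feature map.
#' @param weights Refinement weights ([bfp_refine_weights()]); zero kernel
#'   when `NULL`.
#' @param type `"conv"` or `"nonlocal"`.
#' @return Refined map, same shape.
#' @export
bfp_refine <- function(x, weights = NULL, type = c("conv", "nonlocal")) {
  type <- match.arg(type)
  x <- as_fmap(x)
  C <- fmap_c(x)
  if (is.null(weights)) weights <- bfp_refine_weights(C, type, zero = TRUE)
  if (type == "conv") {
    x + conv2d(x, weights$w, pad = "same")
  } else {
    h <- fmap_h(x); w <- fmap_w(x)
    flat <- matrix(x, h * w, C)
    theta <- flat %*% weights$theta
    phi <- flat %*% weights$phi
    g <- flat %*% weights$g
    att <- theta %*% t(phi) / sqrt(ncol(theta))
    att <- exp(att - apply(att, 1L, max))
    att <- att / rowSums(att)
    x + array((att %*% g) %*% weights$w_out, dim(x))
  }
}

#' @rdname bfp_refine
#' @param C Channel width.
#' @param zero Zero-initialize (identity refinement)?
#' @param seed Integer seed.
#' @export
bfp_refine_weights <- function(C, type = c("conv", "nonlocal"),
                               zero = FALSE, seed = 1L) {
  type <- match.arg(type)
  if (type == "conv") {
    list(w = if (zero) array(0, c(3L, 3L, C, C)) else
      init_conv(3L, 3L, C, C, seed, gain = 0.1))
  } else {
    hid <- max(1L, C %/% 2L)
    mk <- function(k, nin, nout) if (zero) matrix(0, nin, nout) else
      init_mat(nin, nout, child_seed(seed, k), gain = 0.5)
    list(theta = mk(1, C, hid), phi = mk(2, C, hid), g = mk(3, C, hid),
         w_out = mk(4, hid, C))
  }
}

#' Balanced content-aware feature pyramid (CARAFE-BFP)
#'
#' Full neck: top-down pyramid with CARAFE upsampling, Integrate of
#' P2'..P5' at the reference level, Refine, and residual scatter of the
#' refined map back onto every level. P6' passes through unchanged.
#'
#' @param cmaps Named list `C2..C5`.
#' @param weights List with `fpn` ([fpn_weights()]) and optional `refine`
#'   ([bfp_refine_weights()]).
#' @param params [carafe_params()].
#' @param upsampler Upsampler for the top-down pathway.
#' @param refine_type `"conv"` or `"nonlocal"`.
#' @return A `feature_pyramid` with balanced levels P2..P6.
#' @export
carafe_bfp <- function(cmaps, weights, params = carafe_params(),
                       upsampler = c("carafe", "nearest"),
                       refine_type = c("conv", "nonlocal")) {
  upsampler <- match.arg(upsampler)
  refine_type <- match.arg(refine_type)
  pyr <- fpn_topdown(cmaps, weights$fpn, upsampler, params)
  integrated <- bfp_integrate(pyr)
  refined <- bfp_refine(integrated, weights$refine, refine_type)
  levels <- pyr$levels
  for (nm in paste0("P", 2:5)) {
    d <- dim(levels[[nm]])
    add <- if (d[1L] >= dim(refined)[1L]) {
      if (d[1L] == dim(refined)[1L] && d[2L] == dim(refined)[2L]) refined
      else bilinear_resize(refined, d[1L], d[2L])
    } else {
      adaptive_avg_pool(refined, d[1L], d[2L])
    }
    levels[[nm]] <- levels[[nm]] + add
  }
  new_pyramid(levels, pyr$strides)
}

#' Weights for the whole CARAFE-BFP neck
#'
#' @param in_channels Channel widths of C2..C5.
#' @param out_channels Common pyramid width.
#' @param params [carafe_params()].
#' @param refine_type `"conv"` or `"nonlocal"`.
#' @param zero_refine Identity-initialize the refinement?
#' @param seed Integer seed.
#' @export
carafe_bfp_weights <- function(in_channels, out_channels = 32L,
                               params = carafe_params(),
                               refine_type = "conv", zero_refine = FALSE,
                               seed = 1L) {
  list(
    fpn = fpn_weights(in_channels, out_channels, params,
                      child_seed(seed, 1)),
    refine = bfp_refine_weights(out_channels, refine_type,
                                zero = zero_refine, seed = child_seed(seed, 2))
  )
}
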