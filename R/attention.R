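#' Attention gate configuration
#'
#' @param kind One of `"cbam"`, `"se"`, `"gca"`.
#' @param r Channel-reduction factor of the gate MLP (hidden width is
#'   `max(1, floor(C / r))`); 16 by default.
#' @param spatial_kernel Kernel size of CBAM's spatial gate (odd; 7).
#' @return A list of class `attention_config`.
#' @export
attention_config <- function(kind = c("cbam", "se", "gca"), r = 16L,
                             spatial_kernel = 7L) {
  kind <- match.arg(kind)
  assert_that(is_count(r, 1L), "r must be a positive count")
  assert_that(is_count(spatial_kernel, 1L) && spatial_kernel %% 2L == 1L,
              "spatial_kernel must be a positive odd count")
  structure(list(kind = kind, r = r, spatial_kernel = spatial_kernel),
            class = "attention_config")
}

gate_hidden <- function(C, r) max(1L, C %/% r)

#' Squeeze-and-excitation gate parameters
#'
#' Two fully connected layers, `W1` (C x hidden) and `W2` (hidden x C),
#' with hidden width `max(1, floor(C/r))`. `zero = TRUE` gives all-zero
#' weights, under which the gate is exactly `sigmoid(0) = 0.5`.
#'
#' @param C Channel count of the maps the gate will see.
#' @param r Reduction factor.
#' @param seed Integer seed for random initialization.
#' @param zero If `TRUE`, zero-initialize (closed-form gate of 0.5).
#' @return List with `w1`, `w2`.
#' @export
se_params <- function(C, r = 16L, seed = 1L, zero = FALSE) {
  hid <- gate_hidden(C, r)
  if (zero) {
    list(w1 = matrix(0, C, hid), w2 = matrix(0, hid, C))
  } else {
    list(w1 = init_mat(C, hid, child_seed(seed, 1)),
         w2 = init_mat(hid, C, child_seed(seed, 2)))
  }
}

# Shared excitation MLP: sigma(W2 relu(W1 z)).
excite <- function(z, w1, w2) {
  sigmoid(drop(relu(z %*% w1) %*% w2))
}

#' Squeeze-and-excitation channel attention
#'
#' Global average pooling per channel (`z_c = mean(X_c)`), a two-layer
#' bottleneck MLP with ReLU and sigmoid (`s = sigmoid(W2 relu(W1 z))`), and
#' channel-wise rescaling `out_c = s_c * X_c`. Shape-preserving; gates lie
#' strictly in (0, 1).
#'
#' @param x H x W x C feature map.
#' @param params Parameters from [se_params()].
#' @param return_gates If `TRUE`, attach the gate vector as attribute
#'   `"gates"`.
#' @return Gated feature map, same shape as `x`.
#' @export
se_attention <- function(x, params, return_gates = FALSE) {
  x <- as_fmap(x)
  C <- fmap_c(x)
  z <- vapply(seq_len(C), function(c) mean(x[, , c]), numeric(1))
  s <- excite(z, params$w1, params$w2)
  out <- x * rep(s, each = fmap_h(x) * fmap_w(x))
  if (return_gates) attr(out, "gates") <- s
  out
}

#' Global-context channel attention parameters
#'
#' @inheritParams se_params
#' @param variant `"per_channel"` pools with a spatial softmax of each
#'   channel's own activations; `"shared"` uses one learned 1x1 logit map
#'   shared across channels (the classic global-context form). The
#'   per-channel form is the default.
#' @return List with `w1`, `w2`, `variant`, and `wk` (shared variant only).
#' @export
gca_params <- function(C, r = 16L, seed = 1L, zero = FALSE,
                       variant = c("per_channel", "shared")) {
  variant <- match.arg(variant)
  p <- se_params(C, r, seed, zero)
  p$variant <- variant
  if (variant == "shared") {
    p$wk <- if (zero) rep(0, C) else
      drop(init_mat(C, 1L, child_seed(seed, 3)))
  }
  p
}

#' Global-context channel attention
#'
#' Pools a context descriptor `g_c = sum_{i,j} p_{i,j} X_{c,i,j}` where `p`
#' is a spatial softmax (per channel by default; optionally a shared learned
#' logit map), excites it through the same bottleneck MLP as the SE gate
#' (`w = sigmoid(W2 relu(W1 g))`) and rescales each channel. The softmax is
#' computed with max subtraction, so spikes cannot overflow.
#'
#' @inheritParams se_attention
#' @param params Parameters from [gca_params()].
#' @return Gated feature map, same shape as `x`.
#' @export
gca_attention <- function(x, params, return_gates = FALSE) {
  x <- as_fmap(x)
  C <- fmap_c(x)
  g <- gca_context(x, params)
  w <- excite(g, params$w1, params$w2)
  out <- x * rep(w, each = fmap_h(x) * fmap_w(x))
  if (return_gates) attr(out, "gates") <- w
  out
}

# Context pooling used by the GCA gate; exported via gca_attention but kept
# separate so tests can check the softmax-weighted sum directly.
gca_context <- function(x, params = list(variant = "per_channel")) {
  x <- as_fmap(x)
  C <- fmap_c(x)
  if (identical(params$variant, "shared")) {
    logits <- apply(x, c(1L, 2L), function(v) sum(v * params$wk))
    p <- matrix(softmax_vec(as.vector(logits)), fmap_h(x), fmap_w(x))
    vapply(seq_len(C), function(c) sum(p * x[, , c]), numeric(1))
  } else {
    vapply(seq_len(C), function(c) {
      p <- matrix(softmax_vec(as.vector(x[, , c])), fmap_h(x), fmap_w(x))
      sum(p * x[, , c])
    }, numeric(1))
  }
}

#' Convolutional block attention (CBAM) parameters
#'
#' A shared channel MLP (applied to both average- and max-pooled channel
#' descriptors) plus a `k x k` convolution over the 2-channel
#' [channel-average; channel-max] map for the spatial gate.
#'
#' @inheritParams se_params
#' @param spatial_kernel Spatial gate kernel size (odd).
#' @return List with `w1`, `w2`, `w_spatial`, `b_spatial`.
#' @export
cbam_params <- function(C, r = 16L, spatial_kernel = 7L, seed = 1L,
                        zero = FALSE) {
  p <- se_params(C, r, seed, zero)
  p$w_spatial <- if (zero) {
    array(0, c(spatial_kernel, spatial_kernel, 2L, 1L))
  } else {
    init_conv(spatial_kernel, spatial_kernel, 2L, 1L, child_seed(seed, 4))
  }
  p$b_spatial <- 0
  p
}

#' Convolutional block attention (CBAM)
#'
#' Sequential channel-then-spatial gating:
#' `F' = Mc(F) * F`, `F'' = Ms(F') * F'`, where
#' `Mc = sigmoid(MLP(avgpool(F)) + MLP(maxpool(F)))` with a shared
#' bottleneck MLP, and `Ms = sigmoid(conv_k([mean_C; max_C]))` over the
#' channel-wise average and maximum maps. Both gates lie in (0, 1), so for
#' nonnegative inputs the output never exceeds the input elementwise.
#'
#' @inheritParams se_attention
#' @param params Parameters from [cbam_params()].
#' @return Gated feature map, same shape as `x`. With `return_gates = TRUE`
#'   the channel gate (`"gates"`) and spatial gate (`"spatial_gates"`) are
#'   attached as attributes.
#' @export
cbam_attention <- function(x, params, return_gates = FALSE) {
  x <- as_fmap(x)
  C <- fmap_c(x)
  z_avg <- vapply(seq_len(C), function(c) mean(x[, , c]), numeric(1))
  z_max <- vapply(seq_len(C), function(c) max(x[, , c]), numeric(1))
  pre <- drop(relu(z_avg %*% params$w1) %*% params$w2) +
    drop(relu(z_max %*% params$w1) %*% params$w2)
  mc <- sigmoid(pre)
  f1 <- x * rep(mc, each = fmap_h(x) * fmap_w(x))
  sp_avg <- apply(f1, c(1L, 2L), mean)
  sp_max <- apply(f1, c(1L, 2L), max)
  sp_in <- array(c(sp_avg, sp_max), c(dim(sp_avg), 2L))
  ms <- sigmoid(conv2d(sp_in, params$w_spatial, params$b_spatial)[, , 1L])
  out <- f1 * as.vector(ms)
  if (return_gates) {
    attr(out, "gates") <- mc
    attr(out, "spatial_gates") <- ms
  }
  out
}

# Dispatch an attention gate by config.
apply_attention <- function(x, config, params) {
  switch(config$kind,
    cbam = cbam_attention(x, params),
    se = se_attention(x, params),
    gca = gca_attention(x, params),
    abort(paste0("unknown attention kind: ", config$kind),
          class = "foalwatch_config_error")
  )
}

make_attention_params <- function(config, C, seed, zero = FALSE) {
  switch(config$kind,
    cbam = cbam_params(C, config$r, config$spatial_kernel, seed, zero),
    se = se_params(C, config$r, seed, zero),
    gca = gca_params(C, config$r, seed, zero)
  )
}
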