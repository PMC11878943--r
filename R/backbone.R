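#' Bottleneck residual block parameters
#'
#' Builds the weights of one pre-norm bottleneck unit:
#' conv1x1 -> BN -> ReLU -> conv3x3 (carries the stride) -> BN -> ReLU ->
#' conv1x1 -> BN, added to a skip connection and passed through a final
#' ReLU. The skip is the identity when input and output dims agree and a
#' strided 1x1 projection (`ws`) otherwise.
#'
#' @param c_in,c_mid,c_out Channel widths of input, bottleneck and output.
#' @param stride Spatial stride of the block (1 or 2).
#' @param seed Integer seed for weight initialization.
#' @param zero_branch If `TRUE`, the residual branch F is identically zero
#'   (its final conv is zero), leaving only the skip path.
#' @return Parameter list for [residual_block()].
#' @export
residual_block_params <- function(c_in, c_mid, c_out, stride = 1L,
                                  seed = 1L, zero_branch = FALSE) {
  w3 <- if (zero_branch) array(0, c(1L, 1L, c_mid, c_out)) else
    init_conv(1L, 1L, c_mid, c_out, child_seed(seed, 3))
  list(
    w1 = init_conv(1L, 1L, c_in, c_mid, child_seed(seed, 1)),
    w2 = init_conv(3L, 3L, c_mid, c_mid, child_seed(seed, 2)),
    w3 = w3,
    ws = if (c_in != c_out || stride != 1L)
      init_conv(1L, 1L, c_in, c_out, child_seed(seed, 4)) else NULL,
    stride = as.integer(stride),
    c_in = c_in, c_mid = c_mid, c_out = c_out
  )
}

#' Bottleneck residual block
#'
#' `x_out = relu(F(x, {W_i}) + W_s x)` where F is the bottleneck branch and
#' `W_s` is the identity (when dims match) or a 1x1 projection.
#'
#' @param x H x W x C_in feature map.
#' @param params From [residual_block_params()].
#' @return Feature map with the block's output width and stride.
#' @export
residual_block <- function(x, params) {
  x <- as_fmap(x)
  assert_that(fmap_c(x) == params$c_in, "input width mismatch")
  if (is.null(params$ws)) {
    assert_that(params$c_in == params$c_out && params$stride == 1L,
                "identity skip needs matching dims and stride 1")
    skip <- x
  } else {
    skip <- conv2d(x, params$ws, stride = params$stride, pad = 0L)
  }
  f <- conv2d(x, params$w1, pad = 0L)
  f <- relu(batch_norm(f))
  f <- conv2d(f, params$w2, stride = params$stride, pad = "same")
  f <- relu(batch_norm(f))
  f <- conv2d(f, params$w3, pad = 0L)
  f <- batch_norm(f)
  relu(f + skip)
}

#' Build a residual backbone with optional late-stage attention
#'
#' A four-stage bottleneck residual network emitting the C2..C5 maps at
#' strides 4, 8, 16, 32 relative to the input. When `attention` is given,
#' the chosen gate (CBAM, SE or GCA) is appended after every residual unit
#' in stages 3 and 4 only - the high-level, semantically rich stages.
#'
#' @param depth Blocks per stage, e.g. `c(1, 1, 2, 1)` (desk scale) or
#'   `c(3, 4, 23, 3)` (the full 101-layer layout).
#' @param widths Output channels of stages 1..4.
#' @param in_channels Image channels (3).
#' @param attention An [attention_config()] or `NULL`.
#' @param seed Integer seed for all weights.
#' @return A `backbone` object; apply it with [backbone_forward()].
#' @export
build_backbone <- function(depth = c(1L, 1L, 2L, 1L),
                           widths = c(16L, 32L, 64L, 128L),
                           in_channels = 3L, attention = NULL, seed = 1L) {
  assert_that(length(depth) == 4L && all(depth >= 1L),
              "depth must give >= 1 block for each of 4 stages")
  assert_that(length(widths) == 4L, "widths must have 4 entries")
  if (!is.null(attention)) {
    assert_that(inherits(attention, "attention_config"),
                "attention must be an attention_config or NULL")
  }
  stem_w <- init_conv(3L, 3L, in_channels, widths[1L], child_seed(seed, 900))
  stages <- vector("list", 4L)
  attn <- vector("list", 4L)
  c_prev <- widths[1L]
  k <- 0L
  for (s in 1:4) {
    blocks <- vector("list", depth[s])
    gates <- vector("list", depth[s])
    for (b in seq_len(depth[s])) {
      k <- k + 1L
      stride <- if (s > 1L && b == 1L) 2L else 1L
      blocks[[b]] <- residual_block_params(
        c_prev, max(4L, widths[s] %/% 4L), widths[s], stride,
        child_seed(seed, 10L * k))
      c_prev <- widths[s]
      if (!is.null(attention) && s >= 3L) {
        gates[[b]] <- make_attention_params(attention, widths[s],
                                            child_seed(seed, 10L * k + 5L))
      }
    }
    stages[[s]] <- blocks
    attn[[s]] <- gates
  }
  structure(list(stem_w = stem_w, stages = stages, attn = attn,
                 attention = attention, widths = widths, depth = depth,
                 in_channels = in_channels, seed = seed),
            class = "backbone")
}

#' Run a backbone over an image
#'
#' @param backbone From [build_backbone()].
#' @param image H x W x in_channels array with intensities in `[0, 1]`.
#' @return Named list of feature maps `C2`, `C3`, `C4`, `C5` at strides
#'   4, 8, 16, 32.
#' @export
backbone_forward <- function(backbone, image) {
  x <- as_fmap(image)
  assert_that(fmap_c(x) == backbone$in_channels,
              "image channel count does not match the backbone")
  # stem: stride-2 conv + stride-2 max pool => stage 1 sees stride 4
  x <- conv2d(x, backbone$stem_w, stride = 2L, pad = "same")
  x <- relu(batch_norm(x))
  x <- max_pool(x, k = 2L, stride = 2L)
  out <- vector("list", 4L)
  for (s in 1:4) {
    for (b in seq_along(backbone$stages[[s]])) {
      x <- residual_block(x, backbone$stages[[s]][[b]])
      gate <- backbone$attn[[s]][[b]]
      if (!is.null(gate)) x <- apply_attention(x, backbone$attention, gate)
    }
    out[[s]] <- x
  }
  names(out) <- c("C2", "C3", "C4", "C5")
  out
}

# Number of attention gates attached in each stage (diagnostics/tests).
backbone_attention_counts <- function(backbone) {
  vapply(backbone$attn, function(g) sum(!vapply(g, is.null, logical(1))),
         integer(1))
}
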