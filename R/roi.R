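# Multi-channel bilinear gather: sample every channel of x (H x W x C) at
# continuous 0-based coordinates; out-of-range corners read as zero.
gather_bilinear_multi <- function(x, ys, xs) {
  d <- dim(x)
  h <- d[1L]; w <- d[2L]; C <- d[3L]
  xm <- matrix(x, h * w, C)
  n <- length(ys)
  y0 <- floor(ys); x0 <- floor(xs)
  dy <- ys - y0; dx <- xs - x0
  corner <- function(yy, xx) {
    ok <- yy >= 0 & yy <= h - 1 & xx >= 0 & xx <= w - 1
    vals <- matrix(0, n, C)
    if (any(ok)) {
      vals[ok, ] <- xm[yy[ok] + xx[ok] * h + 1, , drop = FALSE]
    }
    vals
  }
  corner(y0, x0) * ((1 - dy) * (1 - dx)) +
    corner(y0, x0 + 1) * ((1 - dy) * dx) +
    corner(y0 + 1, x0) * (dy * (1 - dx)) +
    corner(y0 + 1, x0 + 1) * (dy * dx)
}

#' RoI alignment
#'
#' Pools a region of interest to a fixed `out_size x out_size` grid without
#' coordinate quantization: each output cell averages `sampling_ratio^2`
#' bilinear samples taken at regular positions inside the cell. The box is
#' given in image pixels and divided by `stride` to reach feature-map
#' coordinates. The 14 x 14 default grid preserves the small fetal-sac
#' detail that a 7 x 7 grid washes out.
#'
#' @param map H x W x C feature map.
#' @param box One-row list/tibble with `x, y, w, h` in image pixels
#'   (`w, h > 0`).
#' @param stride Feature-map stride relative to the image.
#' @param out_size Output grid side (14).
#' @param sampling_ratio Bilinear samples per cell side (2).
#' @return out_size x out_size x C array.
#' @export
roi_align <- function(map, box, stride = 1, out_size = 14L,
                      sampling_ratio = 2L) {
  map <- as_fmap(map)
  assert_that(box$w > 0 && box$h > 0, "degenerate box (w or h <= 0)")
  x0 <- box$x / stride; y0 <- box$y / stride
  bw <- box$w / stride / out_size
  bh <- box$h / stride / out_size
  sr <- sampling_ratio
  # sample offsets (cell i, sub-sample s): y0 + (i-1+ (s-0.5)/sr) * bh
  py <- y0 + (rep(seq_len(out_size) - 1L, each = sr) +
                (rep(seq_len(sr), out_size) - 0.5) / sr) * bh - 0.5
  px <- x0 + (rep(seq_len(out_size) - 1L, each = sr) +
                (rep(seq_len(sr), out_size) - 0.5) / sr) * bw - 0.5
  m <- out_size * sr
  ys <- rep(py, times = m)
  xs <- rep(px, each = m)
  vals <- gather_bilinear_multi(map, ys, xs)   # (m*m) x C, rows y-fastest
  C <- fmap_c(map)
  # average sr x sr sub-samples per cell
  pool <- matrix(0, out_size, m)
  for (i in seq_len(out_size)) pool[i, (i - 1L) * sr + seq_len(sr)] <- 1 / sr
  out <- array(0, c(out_size, out_size, C))
  for (c in seq_len(C)) {
    out[, , c] <- pool %*% matrix(vals[, c], m, m) %*% t(pool)
  }
  out
}

#' Generic multi-level RoI extractor (GRoIE) weights
#'
#' Per-level 3 x 3 preprocessing convolutions, softmax-normalized level
#' weights (zero logits = uniform), and a CBAM-style post-processing
#' attention gate on the fused grid.
#'
#' @param C Pyramid channel width.
#' @param n_levels Number of pyramid levels pooled (5).
#' @param seed Integer seed.
#' @param identity_pre Identity-initialize the preprocessing convs?
#' @param post `"cbam"` or `"none"`.
#' @return List with `pre`, `level_logits`, `post`.
#' @export
groie_weights <- function(C, n_levels = 5L, seed = 1L,
                          identity_pre = FALSE, post = c("cbam", "none")) {
  post <- match.arg(post)
  ident <- array(0, c(3L, 3L, C, C))
  for (c in seq_len(C)) ident[2L, 2L, c, c] <- 1
  pre <- lapply(seq_len(n_levels), function(l) {
    if (identity_pre) ident else
      ident + init_conv(3L, 3L, C, C, child_seed(seed, l), gain = 0.1)
  })
  list(pre = pre,
       level_logits = rep(0, n_levels),
       post = if (post == "cbam") cbam_params(C, seed = child_seed(seed, 99))
              else NULL)
}

#' Extract RoI features from every pyramid level (GRoIE)
#'
#' For each proposal: RoI-align the SAME region on every pyramid level
#' (not one assigned level), run each level's preprocessing convolution,
#' fuse by a softmax-weighted sum across levels, and post-process the fused
#' grid with a CBAM-style attention gate. With `weights = NULL` the
#' preprocessing is the identity, the level weights are uniform and no
#' post-processing is applied.
#'
#' @param pyramid A `feature_pyramid`.
#' @param proposals Tibble of boxes (`x, y, w, h` in image pixels).
#' @param weights [groie_weights()] or `NULL`.
#' @param out_size RoI grid side (14).
#' @return List of out_size x out_size x C arrays, one per proposal.
#' @export
groie_extract <- function(pyramid, proposals, weights = NULL,
                          out_size = 14L) {
  assert_that(length(pyramid$levels) >= 1L, "empty pyramid")
  lev_names <- names(pyramid$levels)
  L <- length(lev_names)
  wts <- if (is.null(weights)) rep(1 / L, L) else
    softmax_vec(weights$level_logits)
  lapply(seq_len(nrow(proposals)), function(i) {
    box <- proposals[i, , drop = FALSE]
    fused <- NULL
    for (l in seq_len(L)) {
      grid <- roi_align(pyramid$levels[[l]], box,
                        stride = pyramid$strides[[l]], out_size = out_size)
      if (!is.null(weights)) {
        grid <- conv2d(grid, weights$pre[[l]], pad = "same")
      }
      fused <- if (is.null(fused)) wts[l] * grid else fused + wts[l] * grid
    }
    if (!is.null(weights) && !is.null(weights$post)) {
      fused <- cbam_attention(fused, weights$post)
    }
    fused
  })
}
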