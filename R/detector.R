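# Box <-> delta parameterization (standard two-stage encoding).
encode_deltas <- function(src, gt) {
  scx <- src$x + src$w / 2; scy <- src$y + src$h / 2
  gcx <- gt$x + gt$w / 2; gcy <- gt$y + gt$h / 2
  cbind((gcx - scx) / src$w, (gcy - scy) / src$h,
        log(gt$w / src$w), log(gt$h / src$h))
}

decode_deltas <- function(src, t) {
  scx <- src$x + src$w / 2; scy <- src$y + src$h / 2
  cx <- scx + t[, 1L] * src$w
  cy <- scy + t[, 2L] * src$h
  w <- src$w * exp(pmin(t[, 3L], 4))
  h <- src$h * exp(pmin(t[, 4L], 4))
  tibble(x = cx - w / 2, y = cy - h / 2, w = w, h = h)
}

clip_boxes <- function(boxes, width, height) {
  x0 <- pmin(pmax(boxes$x, 0), width)
  y0 <- pmin(pmax(boxes$y, 0), height)
  x1 <- pmin(pmax(boxes$x + boxes$w, 0), width)
  y1 <- pmin(pmax(boxes$y + boxes$h, 0), height)
  tibble(x = x0, y = y0, w = x1 - x0, h = y1 - y0)
}

#' Greedy non-maximum suppression
#'
#' @param boxes Tibble with `x, y, w, h`.
#' @param scores Scores, same length.
#' @param iou_thr Suppression IoU threshold.
#' @return Indices of the kept boxes, in descending score order.
#' @export
nms <- function(boxes, scores, iou_thr = 0.5) {
  ord <- order(-scores)
  keep <- integer()
  while (length(ord) > 0L) {
    i <- ord[1L]
    keep <- c(keep, i)
    ord <- ord[-1L]
    if (length(ord) == 0L) break
    ious <- box_iou(boxes[ord, , drop = FALSE], boxes[i, , drop = FALSE])
    ord <- ord[ious <= iou_thr]
  }
  keep
}

# Anchor grid for one pyramid level. Rows are ordered anchor-shape-major:
# for each of the A shapes, all cells column-major (row index fastest),
# matching matrix(level, H*W, C) row order.
anchor_grid <- function(h, w, stride, scales, ratios) {
  combos <- expand.grid(scale = scales, ratio = ratios)
  A <- nrow(combos)
  n_cells <- h * w
  ii <- rep(seq_len(h), times = w)
  jj <- rep(seq_len(w), each = h)
  cx <- (jj - 0.5) * stride
  cy <- (ii - 0.5) * stride
  out <- vector("list", A)
  for (a in seq_len(A)) {
    size <- stride * combos$scale[a]
    aw <- size * sqrt(combos$ratio[a])
    ah <- size / sqrt(combos$ratio[a])
    out[[a]] <- tibble(x = cx - aw / 2, y = cy - ah / 2, w = aw, h = ah,
                       cell = seq_len(n_cells), a = a)
  }
  bind_rows(out)
}

#' Configuration of the miniature two-stage detector
#'
#' Defaults give a desk-scale model: a `[1, 1, 2, 1]` residual backbone
#' with CBAM gates in stages 3-4, a 32-channel CARAFE-BFP neck, GRoIE RoI
#' extraction at 14 x 14, and 3 scales x 3 aspect ratios of anchors on
#' P2-P6.
#'
#' @param in_channels Image channels.
#' @param depth,widths Backbone stage layout and widths.
#' @param attention [attention_config()] or `NULL`.
#' @param neck_channels Pyramid width after lateral projection.
#' @param carafe [carafe_params()].
#' @param roi_out RoI grid side (14).
#' @param anchor_scales,anchor_ratios Anchor shape grid (sizes are
#'   `stride * scale`).
#' @param seed Integer seed for all weights.
#' @return List of class `lmpd_config`.
#' @export
lmpd_config <- function(in_channels = 3L, depth = c(1L, 1L, 2L, 1L),
                        widths = c(16L, 32L, 64L, 128L),
                        attention = attention_config("cbam"),
                        neck_channels = 32L, carafe = carafe_params(),
                        roi_out = 14L,
                        anchor_scales = c(6, 9, 13),
                        anchor_ratios = c(0.5, 1, 2), seed = 1L) {
  structure(list(in_channels = in_channels, depth = depth, widths = widths,
                 attention = attention, neck_channels = neck_channels,
                 carafe = carafe, roi_out = roi_out,
                 anchor_scales = anchor_scales,
                 anchor_ratios = anchor_ratios, seed = seed),
            class = "lmpd_config")
}

#' Assemble the miniature parturition detector
#'
#' Composes backbone (+ attention), CARAFE-BFP neck, RPN and GRoIE + box
#' head into one object. The backbone, neck and GRoIE transforms are fixed
#' at assembly (a frozen random feature extractor at desk scale); the RPN
#' head and the classification/regression head are the trainable parts,
#' zero-initialized.
#'
#' @param config An [lmpd_config()].
#' @return An object of class `lmpd_detector`.
#' @export
assemble_lmpd <- function(config = lmpd_config()) {
  seed <- config$seed
  backbone <- build_backbone(config$depth, config$widths,
                             config$in_channels, config$attention,
                             seed = child_seed(seed, 1))
  neck <- carafe_bfp_weights(config$widths, config$neck_channels,
                             config$carafe, seed = child_seed(seed, 2))
  groie <- groie_weights(config$neck_channels, 5L,
                         seed = child_seed(seed, 3))
  A <- length(config$anchor_scales) * length(config$anchor_ratios)
  C <- config$neck_channels
  Ch <- 64L   # frozen RPN hidden width (3x3 conv + ReLU, shared)
  D <- config$roi_out^2 * C
  detector <- list(
    config = config,
    backbone = backbone,
    neck = neck,
    groie = groie,
    rpn_hidden = init_conv(3L, 3L, C, Ch, child_seed(seed, 4)),
    rpn = list(w_obj = matrix(0, Ch, A), b_obj = rep(0, A),
               w_reg = matrix(0, Ch, 4L * A), b_reg = rep(0, 4L * A)),
    head = list(w_cls = matrix(0, D, 3L), b_cls = rep(0, 3L),
                w_reg = matrix(0, D, 4L), b_reg = rep(0, 4L)),
    rpn_norm = NULL,   # optional frozen feature standardization
    head_norm = NULL,
    delta_std = c(0.1, 0.1, 0.2, 0.2),  # box-delta normalization

    classes = c("bg", "MP", "MNP"),
    loss_history = NULL
  )
  class(detector) <- "lmpd_detector"
  detector
}

#' @export
print.lmpd_detector <- function(x, ...) {
  cat(sprintf(
    "<lmpd_detector: depth [%s], widths [%s], %s attention, neck %d ch>\n",
    paste(x$config$depth, collapse = ","),
    paste(x$config$widths, collapse = ","),
    if (is.null(x$config$attention)) "no" else x$config$attention$kind,
    x$config$neck_channels))
  if (!is.null(x$loss_history)) {
    cat(sprintf("  trained %d iterations, loss %.4f -> %.4f\n",
                nrow(x$loss_history), x$loss_history$loss[1L],
                tail(x$loss_history$loss, 1L)))
  }
  invisible(x)
}

#' Forward an image through backbone and neck
#'
#' @param detector An [assemble_lmpd()] object.
#' @param image H x W x C array in `[0, 1]`.
#' @return A `feature_pyramid` (P2-P6).
#' @export
forward_pyramid <- function(detector, image) {
  image <- as_fmap(image)
  assert_that(fmap_h(image) >= 32 && fmap_w(image) >= 32,
              "image smaller than the backbone's minimum stride product")
  cmaps <- backbone_forward(detector$backbone, image)
  carafe_bfp(cmaps, detector$neck, detector$config$carafe)
}

# Standardize an HW x C feature matrix with frozen stats (identity if
# NULL). `gain` rescales rows to a fixed squared norm so that one
# configured learning rate is stable for heads of very different input
# widths (the effective step in prediction space is lr * ||row||^2).
standardize_rows <- function(m, norm, level = NULL) {
  if (is.null(norm)) return(m)
  st <- if (is.null(level)) norm else norm[[level]]
  if (is.null(st)) return(m)
  out <- sweep(sweep(m, 2L, st$mu, "-"), 2L, st$sd, "/")
  if (!is.null(st$gain)) out <- out * st$gain
  out
}

# Frozen RPN intermediate features: shared 3x3 conv + ReLU over a level,
# flattened to one row per spatial cell.
rpn_hidden_features <- function(detector, level_map) {
  fm <- relu(conv2d(level_map, detector$rpn_hidden, pad = "same"))
  d <- dim(fm)
  matrix(fm, d[1L] * d[2L], d[3L])
}

# RPN forward over a pyramid: anchors, objectness scores and box deltas.
rpn_forward <- function(detector, pyramid) {
  levels <- names(pyramid$levels)
  A <- ncol(detector$rpn$w_obj)
  per_level <- lapply(levels, function(nm) {
    fm <- rpn_hidden_features(detector, pyramid$levels[[nm]])
    d <- dim(pyramid$levels[[nm]])
    feats <- standardize_rows(fm, detector$rpn_norm, nm)
    obj <- sweep(feats %*% detector$rpn$w_obj, 2L, detector$rpn$b_obj, "+")
    reg <- sweep(feats %*% detector$rpn$w_reg, 2L, detector$rpn$b_reg, "+")
    anchors <- anchor_grid(d[1L], d[2L], pyramid$strides[[nm]],
                           detector$config$anchor_scales,
                           detector$config$anchor_ratios)
    deltas <- do.call(rbind, lapply(seq_len(A), function(a) {
      reg[, (a - 1L) * 4L + 1:4, drop = FALSE]
    }))
    anchors$score <- sigmoid(as.vector(obj))
    anchors$level <- nm
    list(anchors = anchors, deltas = deltas, feats = feats)
  })
  names(per_level) <- levels
  per_level
}

# Decode, clip and NMS-filter RPN output into proposals.
rpn_proposals <- function(detector, pyramid, width, height,
                          pre_nms = 1000L, post_nms = 50L, nms_thr = 0.7,
                          min_size = 8) {
  rp <- rpn_forward(detector, pyramid)
  anchors <- bind_rows(lapply(rp, function(l) l$anchors))
  deltas <- do.call(rbind, lapply(rp, function(l) l$deltas))
  deltas <- sweep(deltas, 2L, detector$delta_std, "*")
  boxes <- clip_boxes(decode_deltas(anchors, deltas), width, height)
  boxes$score <- anchors$score
  ok <- boxes$w >= min_size & boxes$h >= min_size
  boxes <- boxes[ok, , drop = FALSE]
  if (nrow(boxes) == 0L) return(boxes)
  take <- head(order(-boxes$score), pre_nms)
  boxes <- boxes[take, , drop = FALSE]
  keep <- nms(boxes, boxes$score, nms_thr)
  boxes[head(keep, post_nms), , drop = FALSE]
}

# Flatten GRoIE grids into head-input rows (optionally standardized).
roi_feature_rows <- function(detector, pyramid, proposals) {
  grids <- groie_extract(pyramid, proposals, detector$groie,
                         detector$config$roi_out)
  rows <- do.call(rbind, lapply(grids, as.vector))
  standardize_rows(rows, detector$head_norm)
}

softmax_rows <- function(logits) {
  e <- exp(logits - apply(logits, 1L, max))
  e / rowSums(e)
}

#' Run detection on an image
#'
#' Full two-stage inference: RPN proposals from the pyramid, GRoIE
#' features, class softmax and class-agnostic box regression, then a score
#' threshold and class-wise non-maximum suppression. Deterministic given
#' the weights.
#'
#' @param detector An `lmpd_detector`.
#' @param image H x W x C array; ignored when `pyramid` is supplied.
#' @param score_thr Minimum class score (0.05).
#' @param nms_thr Class-wise NMS IoU threshold (0.5).
#' @param max_dets Detection cap per image (100).
#' @param pyramid Optional precomputed [forward_pyramid()] output.
#' @param width,height Image size (required with `pyramid`).
#' @return Tibble `x, y, w, h, score, label` (possibly zero rows).
#' @export
detect <- function(detector, image = NULL, score_thr = 0.05, nms_thr = 0.5,
                   max_dets = 100L, pyramid = NULL, width = NULL,
                   height = NULL) {
  if (is.null(pyramid)) {
    image <- as_fmap(image)
    height <- fmap_h(image); width <- fmap_w(image)
    pyramid <- forward_pyramid(detector, image)
  }
  empty <- tibble(x = numeric(), y = numeric(), w = numeric(),
                  h = numeric(), score = numeric(), label = character())
  props <- rpn_proposals(detector, pyramid, width, height)
  if (nrow(props) == 0L) return(empty)
  rows <- roi_feature_rows(detector, pyramid, props)
  p <- softmax_rows(sweep(rows %*% detector$head$w_cls, 2L,
                          detector$head$b_cls, "+"))
  t_reg <- sweep(rows %*% detector$head$w_reg, 2L, detector$head$b_reg, "+")
  t_reg <- sweep(t_reg, 2L, detector$delta_std, "*")
  refined <- clip_boxes(decode_deltas(props, t_reg), width, height)
  out <- list()
  for (ci in 2:3) {
    scores <- p[, ci]
    keep <- which(scores >= score_thr & refined$w > 0 & refined$h > 0)
    if (length(keep) == 0L) next
    b <- refined[keep, , drop = FALSE]
    s <- scores[keep]
    kept <- nms(b, s, nms_thr)
    out[[length(out) + 1L]] <- tibble(
      x = b$x[kept], y = b$y[kept], w = b$w[kept], h = b$h[kept],
      score = s[kept], label = detector$classes[ci])
  }
  if (length(out) == 0L) return(empty)
  res <- bind_rows(out)
  res[head(order(-res$score), max_dets), , drop = FALSE]
}

#' Detect over a list of scenes
#'
#' Convenience wrapper producing a detection table (with `image_id`) and a
#' matching ground-truth table for [mean_ap()].
#'
#' @param detector An `lmpd_detector`.
#' @param scenes List of `synthetic_scene` objects (or lists with `image`,
#'   `boxes`, `labels`).
#' @param pyramids Optional list of precomputed pyramids (e.g. from the
#'   trainer's cache).
#' @param ... Passed to [detect()].
#' @return List with `detections` and `ground_truth` tibbles.
#' @export
detect_scenes <- function(detector, scenes, pyramids = NULL, ...) {
  dets <- list(); gts <- list()
  for (i in seq_along(scenes)) {
    sc <- scenes[[i]]
    h <- dim(sc$image)[1L]; w <- dim(sc$image)[2L]
    d <- if (!is.null(pyramids)) {
      detect(detector, pyramid = pyramids[[i]], width = w, height = h, ...)
    } else {
      detect(detector, sc$image, ...)
    }
    if (nrow(d) > 0L) {
      d$image_id <- i
      dets[[length(dets) + 1L]] <- d
    }
    if (nrow(sc$boxes) > 0L) {
      g <- sc$boxes
      g$image_id <- i
      g$label <- sc$labels
      gts[[length(gts) + 1L]] <- g
    }
  }
  empty_d <- tibble(x = numeric(), y = numeric(), w = numeric(),
                    h = numeric(), score = numeric(), label = character(),
                    image_id = integer())
  list(detections = if (length(dets)) bind_rows(dets) else empty_d,
       ground_truth = if (length(gts)) bind_rows(gts) else
         empty_d[, setdiff(names(empty_d), "score")])
}
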