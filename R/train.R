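#' Training configuration
#'
#' SGD with momentum and weight decay. The full-scale reference schedule
#' (learning rate 0.005, momentum 0.9, weight decay 1e-4) is kept as the
#' default; iteration count and batch sizes are desk-scale.
#'
#' @param lr Learning rate (> 0).
#' @param momentum SGD momentum.
#' @param weight_decay L2 weight decay.
#' @param iterations Training iterations (one image per iteration).
#' @param rpn_batch Anchors sampled per iteration.
#' @param roi_batch RoIs sampled per iteration.
#' @param input_size Optional `c(width, height)` to resize inputs to, or
#'   `NULL` to train at the native scene size.
#' @param seed Integer seed driving all sampling.
#' @return List of class `train_config`.
#' @export
train_config <- function(lr = 0.005, momentum = 0.9, weight_decay = 1e-4,
                         iterations = 400L, rpn_batch = 192L,
                         roi_batch = 96L, input_size = NULL, seed = 1L) {
  assert_that(lr >= 0, "lr must be nonnegative")
  structure(list(lr = lr, momentum = momentum,
                 weight_decay = weight_decay,
                 iterations = as.integer(iterations),
                 rpn_batch = as.integer(rpn_batch),
                 roi_batch = as.integer(roi_batch),
                 input_size = input_size, seed = seed),
            class = "train_config")
}

sgd_step <- function(w, v, grad, lr, momentum, weight_decay) {
  v <- momentum * v - lr * (grad + weight_decay * w)
  list(w = w + v, v = v)
}

# Jittered copies of ground-truth boxes plus random negatives: the RoI
# bank the box head trains on (the RPN is trained separately; at inference
# its proposals feed the same head).
make_roi_bank <- function(gt, width, height, n_jit = 10L, n_rand = 10L,
                          seed = 1L) {
  with_seed(seed, {
    rows <- list(gt[, c("x", "y", "w", "h")])
    for (i in seq_len(nrow(gt))) {
      g <- gt[i, ]
      jit <- tibble(
        x = g$x + rnorm(n_jit, 0, 0.08 * g$w),
        y = g$y + rnorm(n_jit, 0, 0.08 * g$h),
        w = g$w * exp(rnorm(n_jit, 0, 0.15)),
        h = g$h * exp(rnorm(n_jit, 0, 0.15)))
      rows[[length(rows) + 1L]] <- jit
      far <- tibble(
        x = g$x + sample(c(-1, 1), n_jit %/% 2, TRUE) * runif(n_jit %/% 2, 0.6, 1.2) * g$w,
        y = g$y + sample(c(-1, 1), n_jit %/% 2, TRUE) * runif(n_jit %/% 2, 0.4, 1.0) * g$h,
        w = g$w * exp(rnorm(n_jit %/% 2, 0, 0.2)),
        h = g$h * exp(rnorm(n_jit %/% 2, 0, 0.2)))
      rows[[length(rows) + 1L]] <- far
      # part crops: small fragments inside the body that the head must
      # reject (they dominate an untrained RPN's proposals)
      n_part <- 6L
      pw <- g$w * runif(n_part, 0.15, 0.5)
      ph <- g$h * runif(n_part, 0.15, 0.6)
      rows[[length(rows) + 1L]] <- tibble(
        x = g$x + runif(n_part, 0, 1) * (g$w - pw),
        y = g$y + runif(n_part, 0, 1) * (g$h - ph),
        w = pw, h = ph)
    }
    rand <- tibble(w = runif(n_rand, 30, 170), h = runif(n_rand, 25, 120))
    rand$x <- runif(n_rand, 0, pmax(1, width - rand$w))
    rand$y <- runif(n_rand, 0, pmax(1, height - rand$h))
    rows[[length(rows) + 1L]] <- rand[, c("x", "y", "w", "h")]
    # context negatives: degenerate whole/half-frame proposals the head
    # must learn to reject
    rows[[length(rows) + 1L]] <- tibble(
      x = c(0, 0, width / 2, 0, 0),
      y = c(0, 0, 0, height / 2, 0),
      w = c(width, width / 2, width / 2, width, width),
      h = c(height, height, height, height / 2, height / 2))
    boxes <- clip_boxes(bind_rows(rows), width, height)
    boxes[boxes$w >= 8 & boxes$h >= 8, , drop = FALSE]
  })
}

# Assign class labels / regression targets to candidate boxes and extract
# their (unstandardized) GRoIE feature rows.
label_bank_boxes <- function(detector, pyramid, boxes, gt) {
  biou <- box_iou_matrix(boxes, gt)
  if (ncol(biou) > 0L) {
    b_max <- apply(biou, 1L, max)
    b_arg <- max.col(biou, ties.method = "first")
  } else {
    b_max <- rep(0, nrow(boxes)); b_arg <- rep(NA_integer_, nrow(boxes))
  }
  positive <- b_max >= 0.5
  cls <- ifelse(positive, gt$class_idx[b_arg], 1L)   # 1 = background
  targets <- matrix(0, nrow(boxes), 4L)
  if (any(positive)) {
    targets[positive, ] <- sweep(encode_deltas(
      boxes[positive, , drop = FALSE], gt[b_arg[positive], , drop = FALSE]),
      2L, detector$delta_std, "/")
  }
  rows <- do.call(rbind, lapply(
    groie_extract(pyramid, boxes, detector$groie, detector$config$roi_out),
    as.vector))
  list(iou = b_max, cls = cls, positive = positive, targets = targets,
       rows = rows)
}

# Per-scene training cache: frozen pyramid, RPN features and anchor
# assignment, and GRoIE feature rows for the RoI bank.
build_scene_cache <- function(detector, scene, seed) {
  img <- as_fmap(scene$image)
  h <- fmap_h(img); w <- fmap_w(img)
  pyramid <- forward_pyramid(detector, img)
  gt <- scene$boxes
  gt$class_idx <- match(scene$labels, detector$classes)  # 2 = MP, 3 = MNP
  # --- RPN side ---
  lev <- names(pyramid$levels)
  feats <- lapply(lev, function(nm) {
    rpn_hidden_features(detector, pyramid$levels[[nm]])
  })
  names(feats) <- lev
  anchors <- bind_rows(lapply(lev, function(nm) {
    d <- dim(pyramid$levels[[nm]])
    a <- anchor_grid(d[1L], d[2L], pyramid$strides[[nm]],
                     detector$config$anchor_scales,
                     detector$config$anchor_ratios)
    a$level <- nm
    a
  }))
  iou_m <- box_iou_matrix(anchors, gt)
  if (ncol(iou_m) > 0L) {
    max_iou <- apply(iou_m, 1L, max)
    argmax <- max.col(iou_m, ties.method = "first")
  } else {
    max_iou <- rep(0, nrow(anchors)); argmax <- rep(NA_integer_, nrow(anchors))
  }
  lab <- rep(-1L, nrow(anchors))            # -1 ignore, 0 neg, 1 pos
  lab[max_iou < 0.3] <- 0L
  lab[max_iou >= 0.7] <- 1L
  if (nrow(gt) > 0L) {
    for (j in seq_len(nrow(gt))) {          # best anchor per GT is positive
      lab[which.max(iou_m[, j])] <- 1L
    }
  }
  pos_idx <- which(lab == 1L)
  rpn_targets <- if (length(pos_idx) > 0L) {
    sweep(encode_deltas(anchors[pos_idx, , drop = FALSE],
                        gt[argmax[pos_idx], , drop = FALSE]),
          2L, detector$delta_std, "/")
  } else {
    matrix(0, 0L, 4L)
  }
  # --- RoI bank ---
  bank <- make_roi_bank(gt, w, h, seed = child_seed(seed, 17))
  lb <- label_bank_boxes(detector, pyramid, bank, gt)
  list(pyramid = pyramid, width = w, height = h, gt = gt,
       feats = feats, anchors = anchors, anchor_label = lab,
       anchor_pos = pos_idx, anchor_neg = which(lab == 0L),
       rpn_targets = rpn_targets,
       bank = bank, bank_iou = lb$iou, bank_cls = lb$cls,
       bank_positive = lb$positive, bank_targets = lb$targets,
       bank_rows = lb$rows)
}

col_sds <- function(m) {
  mu <- colMeans(m)
  sqrt(pmax(colMeans(m^2) - mu^2, 1e-8))
}

#' Desk-scale detector training
#'
#' Trains the RPN head and the classification/box-regression head over the
#' frozen backbone + CARAFE-BFP + GRoIE feature extractor with SGD
#' (momentum, weight decay). The total loss per iteration is the RPN
#' objectness cross-entropy and balanced-L1 anchor regression plus the
#' head's softmax cross-entropy and balanced-L1 box regression, with RoIs
#' drawn by IoU-balanced sampling. Feature standardization constants are
#' estimated once from the frozen features and stored with the detector.
#'
#' @param detector From [assemble_lmpd()].
#' @param scenes Non-empty list of `synthetic_scene` objects (or a
#'   [generate_dataset()] result carrying in-memory scenes).
#' @param config A [train_config()].
#' @return The trained detector; `$loss_history` holds the per-iteration
#'   loss components and `$cache$pyramids` the frozen per-scene pyramids
#'   (reusable for held-in evaluation).
#' @export
train_tiny <- function(detector, scenes, config = train_config()) {
  if (inherits(scenes, "coco_dataset")) {
    scenes <- attr(scenes, "scenes")
  }
  assert_that(length(scenes) >= 1L, "training needs at least one scene")
  if (!is.null(config$input_size)) {
    scenes <- lapply(scenes, function(sc) {
      tw <- config$input_size[1L]; th <- config$input_size[2L]
      fx <- tw / dim(sc$image)[2L]; fy <- th / dim(sc$image)[1L]
      sc$image <- bilinear_resize(sc$image, th, tw)
      sc$boxes <- scale_boxes(sc$boxes, fx, fy)
      sc
    })
  }
  n_sc <- length(scenes)
  caches <- lapply(seq_len(n_sc), function(i) {
    build_scene_cache(detector, scenes[[i]], child_seed(config$seed, i))
  })
  # frozen standardization: per-level RPN features, head rows; rows are
  # rescaled to squared norm ~ head_norm_dim so the configured lr yields
  # a stable effective step for both heads
  norm_dim <- 64
  # regression gradients are rescaled so their effective step stays in the
  # stable regime while the cross-entropy heads enjoy the larger norm
  reg_weight <- 16 / norm_dim
  lev <- names(caches[[1L]]$feats)
  detector$rpn_norm <- setNames(lapply(lev, function(nm) {
    m <- do.call(rbind, lapply(caches, function(cc) cc$feats[[nm]]))
    list(mu = colMeans(m), sd = col_sds(m),
         gain = sqrt(norm_dim / ncol(m)))
  }), lev)
  all_rows <- do.call(rbind, lapply(caches, function(cc) cc$bank_rows))
  detector$head_norm <- list(mu = colMeans(all_rows), sd = col_sds(all_rows),
                             gain = sqrt(norm_dim / ncol(all_rows)))
  for (i in seq_len(n_sc)) {
    for (nm in lev) {
      caches[[i]]$feats[[nm]] <- standardize_rows(caches[[i]]$feats[[nm]],
                                                  detector$rpn_norm, nm)
    }
    caches[[i]]$bank_rows <- standardize_rows(caches[[i]]$bank_rows,
                                              detector$head_norm)
  }
  A <- ncol(detector$rpn$w_obj)
  params <- c(detector$rpn, detector$head)
  names(params) <- c("rpn_w_obj", "rpn_b_obj", "rpn_w_reg", "rpn_b_reg",
                     "head_w_cls", "head_b_cls", "head_w_reg", "head_b_reg")
  vel <- lapply(params, function(p) p * 0)
  hist_rows <- vector("list", config$iterations)
  smp_cfg <- sampler_config(n_samples = config$roi_batch,
                            pos_fraction = 0.5)
  # alternating schedule: once the RPN has had a first training phase,
  # refresh each scene's RoI bank with the RPN's own proposals so the box
  # head trains on the proposal distribution it will face at inference
  refresh_at <- if (config$iterations >= 50L) {
    floor(config$iterations * c(0.4, 0.7)) + 1L
  } else {
    integer()
  }
  for (it in seq_len(config$iterations)) {
    if (it %in% refresh_at) {
      tmp <- detector
      tmp$rpn <- list(w_obj = params$rpn_w_obj, b_obj = params$rpn_b_obj,
                      w_reg = params$rpn_w_reg, b_reg = params$rpn_b_reg)
      for (i in seq_len(n_sc)) {
        cc2 <- caches[[i]]
        props <- rpn_proposals(tmp, cc2$pyramid, cc2$width, cc2$height,
                               post_nms = 25L)
        if (nrow(props) == 0L || nrow(cc2$gt) == 0L) next
        props <- props[, c("x", "y", "w", "h")]
        lb <- label_bank_boxes(detector, cc2$pyramid, props, cc2$gt)
        caches[[i]]$bank <- bind_rows(cc2$bank, props)
        caches[[i]]$bank_iou <- c(cc2$bank_iou, lb$iou)
        caches[[i]]$bank_cls <- c(cc2$bank_cls, lb$cls)
        caches[[i]]$bank_positive <- c(cc2$bank_positive, lb$positive)
        caches[[i]]$bank_targets <- rbind(cc2$bank_targets, lb$targets)
        caches[[i]]$bank_rows <- rbind(
          cc2$bank_rows, standardize_rows(lb$rows, detector$head_norm))
      }
    }
    cc <- caches[[(it - 1L) %% n_sc + 1L]]
    grads <- lapply(params, function(p) p * 0)
    it_seed <- child_seed(config$seed, 1000L + it)
    # ---- RPN objectness + regression ----
    n_pos_take <- min(length(cc$anchor_pos), config$rpn_batch %/% 2L)
    sel <- with_seed(it_seed, {
      pos <- sample_n_of(cc$anchor_pos, n_pos_take)
      neg <- sample_n_of(cc$anchor_neg, config$rpn_batch - length(pos))
      list(pos = pos, neg = neg)
    })
    samp <- c(sel$pos, sel$neg)
    y <- c(rep(1, length(sel$pos)), rep(0, length(sel$neg)))
    rpn_cls_loss <- 0; rpn_reg_loss <- 0
    n_s <- length(samp)
    if (n_s > 0L) {
      sa <- cc$anchors[samp, , drop = FALSE]
      logit <- numeric(n_s)
      frows <- matrix(0, n_s, nrow(params$rpn_w_obj))
      for (r in seq_len(n_s)) {
        f <- cc$feats[[sa$level[r]]][sa$cell[r], ]
        frows[r, ] <- f
        logit[r] <- sum(f * params$rpn_w_obj[, sa$a[r]]) +
          params$rpn_b_obj[sa$a[r]]
      }
      p <- sigmoid(logit)
      rpn_cls_loss <- -mean(y * log(pmax(p, 1e-12)) +
                              (1 - y) * log(pmax(1 - p, 1e-12)))
      g <- (p - y) / n_s
      for (a in unique(sa$a)) {
        rs <- which(sa$a == a)
        grads$rpn_w_obj[, a] <- grads$rpn_w_obj[, a] +
          crossprod(frows[rs, , drop = FALSE], g[rs])
        grads$rpn_b_obj[a] <- grads$rpn_b_obj[a] + sum(g[rs])
      }
      # regression on the sampled positives
      prs <- seq_along(sel$pos)
      if (length(prs) > 0L) {
        tgt_idx <- match(sel$pos, cc$anchor_pos)
        tgt <- cc$rpn_targets[tgt_idx, , drop = FALSE]
        for (a in unique(sa$a[prs])) {
          rs <- prs[sa$a[prs] == a]
          cols <- (a - 1L) * 4L + 1:4
          pred <- sweep(frows[rs, , drop = FALSE] %*%
                          params$rpn_w_reg[, cols, drop = FALSE],
                        2L, params$rpn_b_reg[cols], "+")
          res <- pred - tgt[match(rs, prs), , drop = FALSE]
          rpn_reg_loss <- rpn_reg_loss + sum(balanced_l1_loss(res))
          gr <- reg_weight * balanced_l1_grad(res) / (4L * length(prs))
          grads$rpn_w_reg[, cols] <- grads$rpn_w_reg[, cols] +
            crossprod(frows[rs, , drop = FALSE], gr)
          grads$rpn_b_reg[cols] <- grads$rpn_b_reg[cols] + colSums(gr)
        }
        rpn_reg_loss <- rpn_reg_loss / (4L * length(prs))
      }
    }
    # ---- box head: IoU-balanced sampling + CE + balanced L1 ----
    sel2 <- iou_balanced_sample(cc$bank_iou, cc$bank_positive, smp_cfg,
                                seed = child_seed(config$seed, 2000L + it))
    rows_idx <- c(sel2$pos, sel2$neg)
    head_cls_loss <- 0; head_reg_loss <- 0
    if (length(rows_idx) > 0L) {
      X <- cc$bank_rows[rows_idx, , drop = FALSE]
      cls <- cc$bank_cls[rows_idx]
      Y <- matrix(0, length(rows_idx), 3L)
      Y[cbind(seq_along(cls), cls)] <- 1
      P <- softmax_rows(sweep(X %*% params$head_w_cls, 2L,
                              params$head_b_cls, "+"))
      head_cls_loss <- -mean(log(pmax(P[cbind(seq_along(cls), cls)],
                                      1e-12)))
      G <- (P - Y) / length(rows_idx)
      grads$head_w_cls <- grads$head_w_cls + crossprod(X, G)
      grads$head_b_cls <- grads$head_b_cls + colSums(G)
      prs2 <- which(cls > 1L)
      if (length(prs2) > 0L) {
        Xp <- X[prs2, , drop = FALSE]
        tgt <- cc$bank_targets[rows_idx[prs2], , drop = FALSE]
        pred <- sweep(Xp %*% params$head_w_reg, 2L, params$head_b_reg, "+")
        res <- pred - tgt
        head_reg_loss <- mean(balanced_l1_loss(res))
        gr <- reg_weight * balanced_l1_grad(res) / length(res)
        grads$head_w_reg <- grads$head_w_reg + crossprod(Xp, gr)
        grads$head_b_reg <- grads$head_b_reg + colSums(gr)
      }
    }
    total <- rpn_cls_loss + rpn_reg_loss + head_cls_loss + head_reg_loss
    if (!is.finite(total)) {
      abort(sprintf("training diverged (non-finite loss) at iteration %d",
                    it),
            class = "foalwatch_training_error")
    }
    for (nm in names(params)) {
      st <- sgd_step(params[[nm]], vel[[nm]], grads[[nm]], config$lr,
                     config$momentum, config$weight_decay)
      params[[nm]] <- st$w
      vel[[nm]] <- st$v
    }
    hist_rows[[it]] <- tibble(iteration = it, loss = total,
                              rpn_cls = rpn_cls_loss, rpn_reg = rpn_reg_loss,
                              head_cls = head_cls_loss,
                              head_reg = head_reg_loss)
  }
  detector$rpn <- list(w_obj = params$rpn_w_obj, b_obj = params$rpn_b_obj,
                       w_reg = params$rpn_w_reg, b_reg = params$rpn_b_reg)
  detector$head <- list(w_cls = params$head_w_cls, b_cls = params$head_b_cls,
                        w_reg = params$head_w_reg, b_reg = params$head_b_reg)
  detector$loss_history <- bind_rows(hist_rows)
  detector$cache <- list(pyramids = lapply(caches, function(cc) cc$pyramid),
                         sizes = lapply(caches, function(cc)
                           c(width = cc$width, height = cc$height)))
  detector
}

#' @exportS3Method generics::glance
glance.lmpd_detector <- function(x, ...) {
  h <- x$loss_history
  tibble(
    trained = !is.null(h),
    iterations = if (is.null(h)) 0L else nrow(h),
    initial_loss = if (is.null(h)) NA_real_ else h$loss[1L],
    final_loss = if (is.null(h)) NA_real_ else tail(h$loss, 1L)
  )
}

#' @exportS3Method generics::tidy
tidy.lmpd_detector <- function(x, ...) {
  groups <- list(rpn_w_obj = x$rpn$w_obj, rpn_w_reg = x$rpn$w_reg,
                 head_w_cls = x$head$w_cls, head_w_reg = x$head$w_reg)
  tibble(term = names(groups),
         n_params = vapply(groups, length, integer(1)),
         l2_norm = vapply(groups, function(m) sqrt(sum(m^2)), numeric(1)))
}

#' Plot the training loss curve
#'
#' @param object A trained `lmpd_detector`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.lmpd_detector <- function(object, ...) {
  assert_that(!is.null(object$loss_history), "detector has not been trained")
  ggplot2::ggplot(object$loss_history,
                  ggplot2::aes(x = .data$iteration, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "iteration", y = "total loss",
                  title = "Desk-scale training loss")
}
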