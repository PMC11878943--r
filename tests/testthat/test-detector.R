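test_that("RoIAlign pools without quantization", {
  # constant map: every cell equals the constant
  mapc <- array(4.2, c(8, 8, 2))
  box <- tibble::tibble(x = 3, y = 3, w = 9, h = 9)  # within the stride-2 map
  out <- roi_align(mapc, box, stride = 2)
  expect_equal(dim(out), c(14, 14, 2))
  expect_lt(max(abs(out - 4.2)), 1e-12)

  # output grid is 14 x 14 regardless of box size
  tiny <- roi_align(mapc, tibble::tibble(x = 1, y = 1, w = 2, h = 2))
  expect_equal(dim(tiny), c(14, 14, 2))

  # a horizontal ramp pools to monotonically increasing columns
  ramp <- array(rep(seq_len(8), each = 8), c(8, 8, 1))  # f(x, y) = x
  rr <- roi_align(ramp, tibble::tibble(x = 1, y = 1, w = 6, h = 6))
  expect_true(all(diff(rr[4, , 1]) > 0))

  expect_error(roi_align(mapc, tibble::tibble(x = 0, y = 0, w = 0, h = 3)),
               "degenerate box")
})

test_that("RoIAlign equals the brute-force bilinear oracle", {
  for (seed in 1:3) {
    map <- random_fmap(8, 8, 3, seed = seed)
    box <- withr::with_seed(seed + 10, tibble::tibble(
      x = runif(1, 0, 3), y = runif(1, 0, 3),
      w = runif(1, 2, 5), h = runif(1, 2, 5)))
    got <- roi_align(map, box, stride = 1, out_size = 7L)
    want <- oracle_roi_align(map, box, stride = 1, out_size = 7L)
    expect_lt(max(abs(got - want)), 1e-6)
  }
})

test_that("GRoIE reduces to single-level extraction in its limits", {
  lv <- lapply(1:5, function(l) random_fmap(2^(7 - l), 2^(7 - l), 4,
                                            seed = 20 + l))
  names(lv) <- paste0("P", 2:6)
  pyr <- foalwatch:::new_pyramid(
    lv, stats::setNames(c(4, 8, 16, 32, 64), names(lv)))
  box <- tibble::tibble(x = 12, y = 10, w = 40, h = 30)

  # identical per-level features + uniform weights + identity transforms
  same <- foalwatch:::new_pyramid(
    stats::setNames(rep(list(lv$P3), 5), names(lv)),
    stats::setNames(rep(8, 5), names(lv)))
  w_id <- groie_weights(4, identity_pre = TRUE, post = "none")
  fused <- groie_extract(same, box, w_id)[[1]]
  single <- roi_align(lv$P3, box, stride = 8)
  expect_lt(max(abs(fused - single)), 1e-9)

  # one-hot level weights pick out P3 exactly
  w_hot <- groie_weights(4, identity_pre = TRUE, post = "none")
  w_hot$level_logits <- c(-2000, 0, -2000, -2000, -2000)
  hot <- groie_extract(pyr, box, w_hot)[[1]]
  expect_equal(hot, roi_align(pyr$levels$P3, box, stride = 8),
               tolerance = 1e-12)

  # constant levels fuse to the mean of the constants
  const <- foalwatch:::new_pyramid(
    stats::setNames(lapply(1:5, function(l) array(l, c(8, 8, 2))),
                    names(lv)),
    stats::setNames(rep(4, 5), names(lv)))
  cbox <- tibble::tibble(x = 3, y = 3, w = 18, h = 16)
  fc <- groie_extract(const, cbox, weights = NULL)[[1]]
  expect_lt(max(abs(fc - 3)), 1e-9)

  expect_error(groie_extract(foalwatch:::new_pyramid(list(), c()), box),
               "empty pyramid")
})

test_that("IoU-balanced sampling honours per-bin quotas", {
  # 90 negatives spread evenly over [0, 0.3): 30 per bin, request 30
  iou <- rep(c(0.05, 0.15, 0.25), each = 30)
  pos <- rep(FALSE, 90)
  cfg <- sampler_config(n_samples = 30, pos_fraction = 0)
  got <- iou_balanced_sample(iou, pos, cfg, seed = 1)
  expect_length(got$neg, 30)
  bins <- cut(iou[got$neg], c(0, 0.1, 0.2, 0.3), right = FALSE)
  expect_equal(as.vector(table(bins)), c(10, 10, 10))

  # request above availability returns everything
  all_got <- iou_balanced_sample(iou[1:5], pos[1:5],
                                 sampler_config(n_samples = 50,
                                                pos_fraction = 0),
                                 seed = 2)
  expect_length(all_got$neg, 5)

  # k_bins = 1 degenerates to plain sampling
  plain <- iou_balanced_sample(iou, pos,
                               sampler_config(n_samples = 30,
                                              pos_fraction = 0, k_bins = 1),
                               seed = 3)
  expect_length(plain$neg, 30)

  # quota property across seeds when bins are sufficiently populated
  for (seed in 1:25) {
    s <- iou_balanced_sample(iou, pos, cfg, seed = seed)
    tab <- table(cut(iou[s$neg], c(0, 0.1, 0.2, 0.3), right = FALSE))
    expect_true(all(tab == 10))
  }

  # shortfall redistribution: an empty bin's quota moves to the others
  iou2 <- rep(c(0.05, 0.25), each = 45)   # middle bin empty
  s2 <- iou_balanced_sample(iou2, rep(FALSE, 90), cfg, seed = 4)
  expect_length(s2$neg, 30)
})

test_that("balanced L1 matches its closed form and regularity", {
  alpha <- 0.5; gamma <- 1.5
  expect_equal(balanced_l1_loss(0), 0)
  # continuity at |x| = 1
  expect_lt(abs(balanced_l1_loss(1 - 1e-9) - balanced_l1_loss(1 + 1e-9)),
            1e-7)
  # closed form at x = 2 computed independently
  b <- exp(gamma / alpha) - 1
  want2 <- gamma * 2 + gamma / b - alpha
  expect_equal(balanced_l1_loss(2), want2, tolerance = 1e-12)
  # inner branch closed form at x = 0.5
  want05 <- (alpha / b) * (b * 0.5 + 1) * log(b * 0.5 + 1) - alpha * 0.5
  expect_equal(balanced_l1_loss(0.5), want05, tolerance = 1e-12)

  xs <- seq(-3, 3, by = 0.01)
  vals <- balanced_l1_loss(xs)
  expect_equal(vals, rev(vals))                     # even
  expect_true(all(vals >= 0))
  expect_equal(sum(vals == 0), 1)                   # zero only at x = 0
  # asymptotically linear with slope gamma
  expect_equal(balanced_l1_loss(100) - balanced_l1_loss(99), gamma,
               tolerance = 1e-9)
})

test_that("untrained detectors satisfy the inference contract", {
  det <- assemble_lmpd(lmpd_config(
    depth = c(1, 1, 1, 1), widths = c(8, 8, 16, 16), neck_channels = 8,
    carafe = carafe_params(c_mid = 16), seed = 5))
  img <- generate_scene(scene_spec(width = 128, height = 96, n_mares = 1,
                                   postures = "standing", classes = "MP",
                                   seed = 6))$image
  d1 <- detect(det, img)
  expect_true(all(c("x", "y", "w", "h", "score", "label") %in% names(d1)))
  if (nrow(d1) > 0) {
    expect_true(all(d1$score >= 0 & d1$score <= 1))
    expect_true(all(d1$label %in% c("MP", "MNP")))
  }
  # identical images give identical outputs
  expect_identical(d1, detect(det, img))
  expect_error(detect(det, array(0.5, c(16, 16, 3))), "smaller than")
})

test_that("SGD bookkeeping: lr = 0 freezes, decay-only shrinks", {
  sc <- make_scene_set(2, seed = 40)
  det <- assemble_lmpd(lmpd_config(
    depth = c(1, 1, 1, 1), widths = c(8, 8, 16, 16), neck_channels = 8,
    carafe = carafe_params(c_mid = 16), seed = 7))
  frozen <- train_tiny(det, sc, train_config(lr = 0, iterations = 5,
                                             seed = 8))
  expect_identical(frozen$rpn$w_obj, det$rpn$w_obj)
  expect_identical(frozen$head$w_cls, det$head$w_cls)

  # weight decay with zero data gradient strictly shrinks weight norms
  w <- matrix(1, 3, 3); v <- w * 0
  for (k in 1:5) {
    st <- foalwatch:::sgd_step(w, v, grad = w * 0, lr = 0.1,
                               momentum = 0, weight_decay = 0.1)
    expect_lt(sqrt(sum(st$w^2)), sqrt(sum(w^2)))
    w <- st$w; v <- st$v
  }
})

test_that("tiny training reduces the loss and localizes a held-in mare", {
  sc <- make_scene_set(6, seed = 50)
  det <- assemble_lmpd(lmpd_config(seed = 51))
  trained <- train_tiny(det, sc, train_config(iterations = 320, seed = 52))
  h <- trained$loss_history
  expect_equal(nrow(h), 320L)
  expect_true(all(is.finite(h$loss)))
  expect_lt(mean(tail(h$loss, 20)), mean(head(h$loss, 20)))

  g <- glance(trained)
  expect_true(g$trained)
  expect_s3_class(tidy(trained), "tbl_df")
  expect_s3_class(autoplot(trained), "ggplot")

  # an MP scene the detector trained on yields an overlapping MP box
  mp_idx <- which(vapply(sc, function(s) "MP" %in% s$labels, logical(1)))[1]
  d <- detect(trained, pyramid = trained$cache$pyramids[[mp_idx]],
              width = 384, height = 216)
  gt <- sc[[mp_idx]]$boxes[sc[[mp_idx]]$labels == "MP", ][1, ]
  d_mp <- d[d$label == "MP", ]
  expect_gt(nrow(d_mp), 0)
  best <- max(box_iou(d_mp, gt))
  expect_gte(best, 0.5)
})
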