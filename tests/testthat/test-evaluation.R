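test_that("IoU follows area arithmetic", {
  a <- tibble::tibble(x = 0, y = 0, w = 10, h = 10)
  expect_equal(box_iou(a, a), 1)
  expect_equal(box_iou(a, tibble::tibble(x = 20, y = 0, w = 10, h = 10)), 0)
  expect_equal(box_iou(a, tibble::tibble(x = 5, y = 0, w = 10, h = 10)),
               1 / 3)
})

test_that("matching is greedy in score with single-use ground truth", {
  gt1 <- tibble::tibble(x = 0, y = 0, w = 10, h = 10)
  d_hit <- tibble::tibble(x = 1, y = 0, w = 10, h = 10, score = 0.9)
  m <- match_detections(d_hit, gt1, iou_thr = 0.5)
  expect_equal(unname(m$counts), c(1, 0, 0))

  # two detections on one GT: only the higher-scored is a TP
  d2 <- tibble::tibble(x = c(1, 0.5), y = 0, w = 10, h = 10,
                       score = c(0.6, 0.8))
  m2 <- match_detections(d2, gt1, iou_thr = 0.5)
  expect_equal(m2$tp, c(FALSE, TRUE))
  expect_equal(unname(m2$counts), c(1, 1, 0))

  gt3 <- tibble::tibble(x = c(0, 20, 40), y = 0, w = 10, h = 10)
  m3 <- match_detections(d_hit[0, ], gt3, iou_thr = 0.5)
  expect_equal(unname(m3$counts["FN"]), 3)
})

test_that("average precision matches hand-derived cases", {
  # single TP covering the only GT
  expect_equal(average_precision(0.9, TRUE, 1), 1)
  # FP ranked above the TP on one GT: 11-point AP = 0.5
  expect_equal(average_precision(c(0.9, 0.8), c(FALSE, TRUE), 1), 0.5)
  # no TP at all
  expect_equal(average_precision(c(0.9, 0.8), c(FALSE, FALSE), 5), 0)
  # undefined when there are no positives
  ap0 <- average_precision(numeric(), logical(), 0)
  expect_true(is.na(ap0))
  expect_true(attr(ap0, "undefined"))
})

test_that("both interpolation modes agree with brute-force oracles", {
  for (seed in 1:5) {
    n <- 40
    dat <- withr::with_seed(seed, list(scores = runif(n),
                                       tp = runif(n) < 0.4))
    n_pos <- sum(dat$tp) + withr::with_seed(seed + 99, sample(0:3, 1))
    if (n_pos == 0) n_pos <- 1
    expect_equal(average_precision(dat$scores, dat$tp, n_pos, "11point"),
                 oracle_ap_11pt(dat$scores, dat$tp, n_pos),
                 tolerance = 1e-12)
    expect_equal(average_precision(dat$scores, dat$tp, n_pos, "all_points"),
                 oracle_ap_area(dat$scores, dat$tp, n_pos),
                 tolerance = 1e-12)
  }
})

test_that("AP is stable under trailing zero-score FPs and score-tie order", {
  scores <- c(0.9, 0.7, 0.6)
  tp <- c(TRUE, TRUE, FALSE)
  base <- average_precision(scores, tp, 2)
  padded <- average_precision(c(scores, 1e-9, 1e-9), c(tp, FALSE, FALSE), 2)
  expect_equal(padded, base, tolerance = 1e-12)

  # dense curves: the two modes agree within 0.1
  n <- 200
  dense <- withr::with_seed(7, list(s = runif(n), tp = runif(n) < 0.5))
  np <- sum(dense$tp)
  expect_lt(abs(average_precision(dense$s, dense$tp, np, "11point") -
                  average_precision(dense$s, dense$tp, np, "all_points")),
            0.1)
})

test_that("mean AP summarizes classes and thresholds as percentages", {
  gt <- tibble::tibble(image_id = c(1, 1, 2), label = c("MP", "MNP", "MNP"),
                       x = c(0, 50, 10), y = c(0, 50, 10), w = 20, h = 20)
  perfect <- dplyr::mutate(gt, score = 0.99)
  rep1 <- mean_ap(gt, perfect)
  expect_equal(rep1$mAP, 100)
  expect_equal(rep1$AR, 100)
  expect_s3_class(glance(rep1), "tbl_df")
  expect_equal(nrow(tidy(rep1)), 2 * 10)

  # detections only for MP: the MNP class scores zero
  mp_only <- perfect[perfect$label == "MP", ]
  rep2 <- mean_ap(gt, mp_only)
  expect_equal(rep2$mAP_MNP, 0)
  expect_equal(rep2$mAP_MP, 100)

  expect_error(mean_ap(gt, dplyr::mutate(perfect, label = "horse")),
               "unknown category")
})

test_that("mean AP equals an independent exhaustive recomputation", {
  # randomized fixture: boxes drifted off their GTs, scores random
  set.seed(21)
  gt <- tibble::tibble(
    image_id = rep(1:5, each = 3),
    label = rep(c("MP", "MNP", "MNP"), 5),
    x = runif(15, 0, 300), y = runif(15, 0, 150),
    w = runif(15, 30, 80), h = runif(15, 20, 60))
  dets <- dplyr::mutate(gt,
                        x = x + rnorm(15, 0, 8), y = y + rnorm(15, 0, 8),
                        w = w * exp(rnorm(15, 0, 0.2)),
                        h = h * exp(rnorm(15, 0, 0.2)),
                        score = runif(15))
  dets <- dets[sample(15), ]
  got <- mean_ap(gt, dets)

  # oracle: per class x threshold, exhaustive matching + 11-pt AP
  oracle_cells <- c()
  for (cls in c("MP", "MNP")) {
    for (thr in seq(0.5, 0.95, by = 0.05)) {
      sc <- c(); tp <- c(); n_pos <- 0
      for (img in 1:5) {
        g <- gt[gt$image_id == img & gt$label == cls, ]
        d <- dets[dets$image_id == img & dets$label == cls, ]
        n_pos <- n_pos + nrow(g)
        if (nrow(d) == 0) next
        d <- d[order(-d$score), ]
        taken <- rep(FALSE, nrow(g))
        for (k in seq_len(nrow(d))) {
          ious <- vapply(seq_len(nrow(g)), function(j) {
            box_iou(d[k, ], g[j, ])
          }, numeric(1))
          ious[taken] <- -1
          jbest <- which.max(ious)
          hit <- length(ious) > 0 && ious[jbest] >= thr
          if (hit) taken[jbest] <- TRUE
          sc <- c(sc, d$score[k]); tp <- c(tp, hit)
        }
      }
      oracle_cells <- c(oracle_cells, oracle_ap_11pt(sc, tp, n_pos))
    }
  }
  expect_equal(got$mAP, 100 * mean(oracle_cells), tolerance = 1e-9)
})

test_that("recall and average recall follow their definitions", {
  expect_equal(recall_from_counts(49, 1), 0.98)
  expect_error(recall_from_counts(0, 0), "TP \\+ FN > 0")
  qs <- tibble::tibble(tp = c(10, 5), fn = c(0, 5))
  expect_equal(average_recall(qs), 0.75)
  expect_warning(
    ar <- average_recall(tibble::tibble(tp = c(10, 0), fn = c(0, 0))),
    "skipped")
  expect_equal(ar, 1)
})
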