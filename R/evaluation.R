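#' Intersection over union of two boxes
#'
#' Boxes are `(x, y, w, h)` in pixels, top-left origin, half-open extents.
#' Vectorized over `a` (a data frame of boxes) against a single box `b`, or
#' scalar for two single boxes.
#'
#' @param a,b Data frames (or one-row lists) with columns `x, y, w, h`.
#' @return Numeric IoU value(s) in `[0, 1]`.
#' @export
box_iou <- function(a, b) {
  ix <- pmax(0, pmin(a$x + a$w, b$x + b$w) - pmax(a$x, b$x))
  iy <- pmax(0, pmin(a$y + a$h, b$y + b$h) - pmax(a$y, b$y))
  inter <- ix * iy
  union <- a$w * a$h + b$w * b$h - inter
  ifelse(union > 0, inter / union, 0)
}

# IoU matrix: rows = boxes in `a`, cols = boxes in `b`.
box_iou_matrix <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(matrix(0, nrow(a), nrow(b)))
  out <- matrix(0, nrow(a), nrow(b))
  for (j in seq_len(nrow(b))) {
    out[, j] <- box_iou(a, b[j, , drop = FALSE])
  }
  out
}

#' Greedy score-ordered matching of detections to ground truth
#'
#' Single class, single image. Detections are processed in descending
#' score; each one claims the not-yet-matched ground-truth box of highest
#' IoU, provided that IoU reaches `iou_thr` (ties on IoU go to the lower
#' GT index). Every GT box is matched at most once.
#'
#' @param dets Tibble with `x, y, w, h, score`.
#' @param gts Tibble with `x, y, w, h`.
#' @param iou_thr IoU threshold for a match.
#' @return List with `tp` (logical per detection, in the original row
#'   order), `counts` (`TP`, `FP`, `FN`), and `matched_gt` (GT row index or
#'   NA per detection).
#' @export
match_detections <- function(dets, gts, iou_thr = 0.5) {
  nd <- nrow(dets); ng <- nrow(gts)
  tp <- logical(nd)
  matched_gt <- rep(NA_integer_, nd)
  if (nd > 0L && ng > 0L) {
    ord <- order(-dets$score)
    iou_m <- box_iou_matrix(dets, gts)
    gt_taken <- logical(ng)
    for (i in ord) {
      ious <- iou_m[i, ]
      ious[gt_taken] <- -1
      j <- which.max(ious)  # ties -> lowest index
      if (ious[j] >= iou_thr) {
        gt_taken[j] <- TRUE
        tp[i] <- TRUE
        matched_gt[i] <- j
      }
    }
  }
  counts <- c(TP = sum(tp), FP = nd - sum(tp), FN = ng - sum(tp))
  list(tp = tp, counts = counts, matched_gt = matched_gt)
}

#' Average precision from ranked detections
#'
#' Builds the precision-recall curve from score-ranked TP/FP flags and
#' summarizes it either by 11-point interpolation (`mean over r in 0, 0.1,
#' ..., 1 of the max precision at recall >= r`) or by the area form
#' `sum p_i * delta r_i` with right-max interpolated precision
#' (`all_points`).
#'
#' @param scores Detection scores.
#' @param tp Logical TP flag per detection.
#' @param n_pos Number of positive (ground-truth) instances.
#' @param interpolation `"11point"` (default) or `"all_points"`.
#' @return AP in `[0, 1]`, or `NA` (with attribute `undefined = TRUE`) when
#'   `n_pos == 0`.
#' @export
average_precision <- function(scores, tp, n_pos,
                              interpolation = c("11point", "all_points")) {
  interpolation <- match.arg(interpolation)
  if (n_pos == 0L) {
    return(structure(NA_real_, undefined = TRUE))
  }
  if (length(scores) == 0L) return(0)
  ord <- order(-scores)
  tp <- tp[ord]
  cum_tp <- cumsum(tp)
  cum_fp <- cumsum(!tp)
  recall <- cum_tp / n_pos
  precision <- cum_tp / (cum_tp + cum_fp)
  if (interpolation == "11point") {
    pts <- seq(0, 1, by = 0.1)
    mean(vapply(pts, function(r) {
      ok <- recall >= r - 1e-12
      if (any(ok)) max(precision[ok]) else 0
    }, numeric(1)))
  } else {
    # right-max interpolated precision, integrated over recall
    p_int <- rev(cummax(rev(precision)))
    r_prev <- c(0, head(recall, -1))
    sum((recall - r_prev) * p_int)
  }
}

canonical_categories <- function() {
  tibble(id = c(1L, 2L), name = c("MP", "MNP"))
}

resolve_category <- function(x) {
  cats <- canonical_categories()
  if (is.numeric(x)) {
    assert_that(all(x %in% cats$id), "unknown category id")
    as.integer(x)
  } else {
    assert_that(all(x %in% cats$name), "unknown category name")
    cats$id[match(x, cats$name)]
  }
}

# Pool per-image matches for one class at one IoU threshold.
pool_class_matches <- function(gt, dets, class_id, iou_thr, max_dets) {
  image_ids <- union(unique(gt$image_id), unique(dets$image_id))
  scores <- numeric(0); tps <- logical(0); n_pos <- 0L
  for (img in image_ids) {
    g <- gt[gt$image_id == img & gt$category_id == class_id, , drop = FALSE]
    d <- dets[dets$image_id == img & dets$category_id == class_id, ,
              drop = FALSE]
    if (nrow(d) > max_dets) {
      d <- d[order(-d$score)[seq_len(max_dets)], , drop = FALSE]
    }
    n_pos <- n_pos + nrow(g)
    if (nrow(d) > 0L) {
      m <- match_detections(d, g, iou_thr)
      scores <- c(scores, d$score)
      tps <- c(tps, m$tp)
    }
  }
  list(scores = scores, tp = tps, n_pos = n_pos)
}

#' COCO-style mean average precision and average recall
#'
#' AP is computed per class and IoU threshold by pooling detections across
#' images in score order; mAP is the mean over both classes and the
#' thresholds `0.50, 0.55, ..., 0.95`. `mAP50/75/90` are the class means at
#' a single threshold, `mAP_MP` / `mAP_MNP` the per-class means over all
#' thresholds. AR is the mean recall over the same class x threshold grid.
#' All summaries are reported as percentages.
#'
#' @param gt Tibble of ground truth: `image_id, category_id` (or `label`),
#'   `x, y, w, h`.
#' @param dets Tibble of detections: same box columns plus `score`.
#' @param iou_set IoU thresholds (default `seq(0.5, 0.95, 0.05)`).
#' @param interpolation Passed to [average_precision()].
#' @param max_dets Per-image detection cap (100).
#' @return An `eval_report`: list with the summary percentages and a
#'   `per_cell` tibble of AP/recall per class and threshold. Supports
#'   [tidy()] and [glance()].
#' @export
mean_ap <- function(gt, dets, iou_set = seq(0.5, 0.95, by = 0.05),
                    interpolation = c("11point", "all_points"),
                    max_dets = 100L) {
  interpolation <- match.arg(interpolation)
  gt <- normalize_box_table(gt, scored = FALSE)
  dets <- normalize_box_table(dets, scored = TRUE)
  cats <- canonical_categories()
  cells <- list()
  k <- 0L
  for (ci in seq_len(nrow(cats))) {
    for (thr in iou_set) {
      pooled <- pool_class_matches(gt, dets, cats$id[ci], thr, max_dets)
      ap <- average_precision(pooled$scores, pooled$tp, pooled$n_pos,
                              interpolation)
      rec <- if (pooled$n_pos > 0L) sum(pooled$tp) / pooled$n_pos else
        NA_real_
      k <- k + 1L
      cells[[k]] <- tibble(class = cats$name[ci], iou = thr,
                           ap = as.numeric(ap), recall = rec,
                           n_pos = pooled$n_pos)
    }
  }
  per_cell <- bind_rows(cells)
  # classes absent from the GT contribute no cells to the averages
  defined <- per_cell[!is.na(per_cell$ap) | per_cell$n_pos > 0, , drop = FALSE]
  defined$ap[is.na(defined$ap)] <- 0
  summ_at <- function(thr) 100 * mean(defined$ap[defined$iou == thr])
  summ_class <- function(cl) {
    v <- defined$ap[defined$class == cl]
    if (length(v) == 0L) NA_real_ else 100 * mean(v)
  }
  report <- list(
    mAP = 100 * mean(defined$ap),
    mAP50 = summ_at(0.50),
    mAP75 = if (0.75 %in% iou_set) summ_at(0.75) else NA_real_,
    mAP90 = if (0.90 %in% iou_set) summ_at(0.90) else NA_real_,
    mAP_MP = summ_class("MP"),
    mAP_MNP = summ_class("MNP"),
    AR = 100 * mean(defined$recall, na.rm = TRUE),
    per_cell = per_cell,
    interpolation = interpolation
  )
  structure(report, class = "eval_report")
}

# Accept either `category_id` or `label` columns; emit canonical ids.
normalize_box_table <- function(x, scored) {
  x <- as_tibble(x)
  needed <- c("image_id", "x", "y", "w", "h", if (scored) "score")
  assert_that(all(needed %in% names(x)),
              paste("box table needs columns:", paste(needed, collapse = ", ")))
  if (!"category_id" %in% names(x)) {
    assert_that("label" %in% names(x),
                "box table needs a category_id or label column")
    x$category_id <- resolve_category(x$label)
  } else {
    x$category_id <- resolve_category(x$category_id)
  }
  x
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "<eval_report (%s)>\n  mAP %.2f%%  mAP50 %.2f%%  mAP75 %.2f%%  mAP90 %.2f%%\n  mAP-MP %.2f%%  mAP-MNP %.2f%%  AR %.2f%%\n",
    x$interpolation, x$mAP, x$mAP50, x$mAP75, x$mAP90, x$mAP_MP, x$mAP_MNP,
    x$AR))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.eval_report <- function(x, ...) {
  x$per_cell
}

#' @exportS3Method generics::glance
glance.eval_report <- function(x, ...) {
  tibble(mAP = x$mAP, mAP50 = x$mAP50, mAP75 = x$mAP75, mAP90 = x$mAP90,
         mAP_MP = x$mAP_MP, mAP_MNP = x$mAP_MNP, AR = x$AR)
}

#' Recall and average recall
#'
#' `recall_from_counts` is `TP / (TP + FN)`. `average_recall` averages the
#' per-query recalls (one query per IoU threshold); queries with a zero
#' denominator are skipped with a warning.
#'
#' @param tp,fn True-positive and false-negative counts.
#' @return Recall in `[0, 1]`.
#' @export
recall_from_counts <- function(tp, fn) {
  assert_that(tp + fn > 0, "recall needs TP + FN > 0")
  tp / (tp + fn)
}

#' @rdname recall_from_counts
#' @param queries Tibble with columns `tp` and `fn`, one row per query.
#' @export
average_recall <- function(queries) {
  ok <- (queries$tp + queries$fn) > 0
  if (!all(ok)) {
    warn(sprintf("%d quer%s with no positives skipped", sum(!ok),
                 if (sum(!ok) == 1) "y" else "ies"))
  }
  assert_that(any(ok), "no query has positives")
  mean(queries$tp[ok] / (queries$tp[ok] + queries$fn[ok]))
}
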