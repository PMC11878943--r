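# Shared fixture builders (everything is generated in code at test time).

# A mixed batch of stable scenes: 1-3 mares, alternating MP scenes, every
# fifth scene in night mode. Deterministic in `seed`.
make_scene_set <- function(n, seed = 3L) {
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      nm <- 1L + (i %% 3L)
      post <- sample(c("standing", "recumbent"), nm, replace = TRUE)
      cls <- rep("MNP", nm)
      if (i %% 2L == 1L) cls[1L] <- "MP"
      generate_scene(scene_spec(
        n_mares = nm, postures = post, classes = cls,
        lighting = if (i %% 5L == 0L) "night" else "day",
        seed = seed * 1000L + i))
    })
  })
}

random_fmap <- function(h, w, c, seed = 1L, positive = FALSE) {
  withr::with_seed(seed, {
    v <- rnorm(h * w * c)
    if (positive) v <- abs(v)
    array(v, c(h, w, c))
  })
}

# Records-only COCO dataset: n images, one annotation per image with the
# given label sequence (recycled).
records_dataset <- function(n, labels = c("MP", "MNP"), width = 384,
                            height = 216) {
  labels <- rep_len(labels, n)
  images <- tibble::tibble(id = seq_len(n),
                           file_name = sprintf("img_%05d.png", seq_len(n)),
                           width = width, height = height)
  annotations <- tibble::tibble(
    id = seq_len(n), image_id = seq_len(n),
    category_id = ifelse(labels == "MP", 1L, 2L),
    x = 10, y = 10, w = 50, h = 40, area = 2000)
  coco_dataset(images, annotations)
}

# Independent brute-force window-rule oracle: first window of length W
# whose MP count strictly exceeds theta * W (exact arithmetic guard).
oracle_first_window <- function(labels, theta, W) {
  n <- length(labels)
  if (n < W) return(NULL)
  for (w in seq_len(n - W + 1L)) {
    count <- sum(labels[w:(w + W - 1L)] == "MP")
    if (count - theta * W > 1e-9) return(w)
  }
  NULL
}

# Independent brute-force bilinear interpolation at one 0-based point.
oracle_bilinear <- function(m, y, x) {
  h <- nrow(m); w <- ncol(m)
  y0 <- floor(y); x0 <- floor(x)
  val <- function(yy, xx) {
    if (yy < 0 || yy > h - 1 || xx < 0 || xx > w - 1) 0 else m[yy + 1, xx + 1]
  }
  dy <- y - y0; dx <- x - x0
  val(y0, x0) * (1 - dy) * (1 - dx) + val(y0, x0 + 1) * (1 - dy) * dx +
    val(y0 + 1, x0) * dy * (1 - dx) + val(y0 + 1, x0 + 1) * dy * dx
}

# Independent brute-force RoIAlign oracle (loops, no vectorization).
oracle_roi_align <- function(map, box, stride = 1, out_size = 14L,
                             sampling_ratio = 2L) {
  C <- dim(map)[3]
  out <- array(0, c(out_size, out_size, C))
  bw <- box$w / stride / out_size
  bh <- box$h / stride / out_size
  for (c in seq_len(C)) {
    for (i in seq_len(out_size)) {
      for (j in seq_len(out_size)) {
        acc <- 0
        for (si in seq_len(sampling_ratio)) {
          for (sj in seq_len(sampling_ratio)) {
            y <- box$y / stride + (i - 1 + (si - 0.5) / sampling_ratio) * bh - 0.5
            x <- box$x / stride + (j - 1 + (sj - 0.5) / sampling_ratio) * bw - 0.5
            acc <- acc + oracle_bilinear(map[, , c], y, x)
          }
        }
        out[i, j, c] <- acc / sampling_ratio^2
      }
    }
  }
  out
}

# Independent 11-point AP oracle: explicit max-precision-to-the-right scan.
oracle_ap_11pt <- function(scores, tp, n_pos) {
  ord <- order(-scores)
  tp <- tp[ord]
  rec <- cumsum(tp) / n_pos
  prec <- cumsum(tp) / seq_along(tp)
  total <- 0
  for (r in seq(0, 1, by = 0.1)) {
    pmax_r <- 0
    for (k in seq_along(rec)) {
      if (rec[k] >= r - 1e-12 && prec[k] > pmax_r) pmax_r <- prec[k]
    }
    total <- total + pmax_r
  }
  total / 11
}

# Independent area-form AP oracle (sum of p_i * delta r_i with right-max
# interpolated precision), computed point by point.
oracle_ap_area <- function(scores, tp, n_pos) {
  ord <- order(-scores)
  tp <- tp[ord]
  rec <- cumsum(tp) / n_pos
  prec <- cumsum(tp) / seq_along(tp)
  total <- 0
  r_prev <- 0
  for (k in seq_along(rec)) {
    p_right <- max(prec[k:length(prec)])
    total <- total + (rec[k] - r_prev) * p_right
    r_prev <- rec[k]
  }
  total
}
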