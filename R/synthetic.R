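#' Specification of a synthetic stable scene
#'
#' Describes one rendered stable scene: image size, the mares present
#' (posture and parturition class each), lighting and noise. The default
#' 384 x 216 size matches the curated working resolution of the detection
#' pipeline. Scenes hold 0-4 mares, mirroring pens in which up to four
#' mares move freely.
#'
#' @param width,height Image size in pixels (>= 32).
#' @param n_mares Number of mares, 0-4.
#' @param postures Character vector, one of `"standing"`, `"recumbent"`
#'   per mare.
#' @param classes Character vector, `"MP"` (parturition: visible fetal sac)
#'   or `"MNP"` per mare.
#' @param lighting `"day"` (colour) or `"night"` (grayscale + noise).
#' @param noise_sd Additive pixel noise SD (intensity units in `[0, 1]`).
#' @param seed Integer seed; equal specs (including seed) render
#'   bit-identical scenes.
#' @return List of class `scene_spec`.
#' @export
scene_spec <- function(width = 384L, height = 216L, n_mares = 1L,
                       postures = rep("standing", n_mares),
                       classes = rep("MNP", n_mares),
                       lighting = c("day", "night"), noise_sd = 0.02,
                       seed = 1L) {
  lighting <- match.arg(lighting)
  assert_that(width >= 32L && height >= 32L, "width and height must be >= 32")
  assert_that(is_count(n_mares, 0L) && n_mares <= 4L,
              "n_mares must be a count between 0 and 4")
  assert_that(length(postures) == n_mares && length(classes) == n_mares,
              "n_mares, postures and classes must have matching lengths")
  assert_that(all(postures %in% c("standing", "recumbent")),
              "postures must be standing or recumbent")
  assert_that(all(classes %in% c("MP", "MNP")),
              "classes must be MP or MNP")
  assert_that(noise_sd >= 0, "noise_sd must be nonnegative")
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_mares = as.integer(n_mares), postures = postures,
                 classes = classes, lighting = lighting,
                 noise_sd = noise_sd, seed = seed),
            class = "scene_spec")
}

# Geometric layout of a scene: mare body/sac ellipses and tight boxes.
# Mares are placed one per quadrant (jittered) so 1-4 bodies fit a pen
# without degenerate overlap; the rear (sac side) always faces +x.
scene_layout <- function(spec) {
  with_seed(spec$seed, {
    W <- spec$width; H <- spec$height
    n <- spec$n_mares
    mares <- vector("list", n)
    if (n > 0L) {
      qx <- c(0.25, 0.75, 0.25, 0.75)
      qy <- c(0.30, 0.30, 0.72, 0.72)
      ord <- sample.int(4L, n)
      for (i in seq_len(n)) {
        len <- runif(1, 0.28, 0.38) * W
        aspect <- if (spec$postures[i] == "standing") 1.5 else 2.6
        a <- len / 2                      # semi-axis along the body (+x)
        b <- len / (2 * aspect)
        cx <- qx[ord[i]] * W + runif(1, -0.04, 0.04) * W
        cy <- qy[ord[i]] * H + runif(1, -0.05, 0.05) * H
        # keep the body inside the frame
        cx <- min(max(cx, a + 2), W - a - 2)
        cy <- min(max(cy, b + 2), H - b - 2)
        sac <- NULL
        if (spec$classes[i] == "MP") {
          sac_r <- runif(1, 0.10, 0.15) * len / 2   # 10-15% of body length
          sac <- list(cx = cx + a - sac_r - 1, cy = cy, r = sac_r)
        }
        x0 <- cx - a; x1 <- cx + a
        y0 <- cy - b; y1 <- cy + b
        if (!is.null(sac)) {
          x1 <- max(x1, sac$cx + sac$r)
          y0 <- min(y0, sac$cy - sac$r); y1 <- max(y1, sac$cy + sac$r)
        }
        mares[[i]] <- list(cx = cx, cy = cy, a = a, b = b, sac = sac,
                           class = spec$classes[i],
                           posture = spec$postures[i],
                           box = c(x = x0, y = y0, w = x1 - x0, h = y1 - y0))
      }
    }
    noise_seed <- sample.int(1e6, 1)
    list(mares = mares, noise_seed = noise_seed)
  })
}

#' Render a synthetic stable scene
#'
#' Draws each mare as a filled ellipse (standing bodies are rounder,
#' recumbent ones flatter), with parturition (MP) mares carrying a small
#' bright fetal-sac blob at the rear of the body - the small-feature regime
#' the detector must resolve. Day scenes are in colour; night scenes are
#' grayscale (equal channels) with additive sensor noise. Deterministic for
#' a fixed spec.
#'
#' @param spec A [scene_spec()].
#' @return List of class `synthetic_scene`: `image` (H x W x 3 array in
#'   `[0, 1]`), `boxes` (tibble `x, y, w, h`, 0-based pixels), `labels`
#'   (character), `spec`.
#' @export
generate_scene <- function(spec) {
  layout <- scene_layout(spec)
  W <- spec$width; H <- spec$height
  night <- spec$lighting == "night"
  bg <- if (night) c(0.22, 0.22, 0.22) else c(0.32, 0.30, 0.24)
  body <- if (night) c(0.58, 0.58, 0.58) else c(0.52, 0.42, 0.33)
  sac_col <- if (night) c(0.95, 0.95, 0.95) else c(0.95, 0.94, 0.90)
  xs <- matrix(rep(seq_len(W) - 0.5, each = H), H, W)   # pixel centres
  ys <- matrix(rep(seq_len(H) - 0.5, times = W), H, W)
  img <- array(0, c(H, W, 3L))
  for (c in 1:3) img[, , c] <- bg[c]
  for (m in layout$mares) {
    inside <- ((xs - m$cx) / m$a)^2 + ((ys - m$cy) / m$b)^2 <= 1
    for (c in 1:3) {
      ch <- img[, , c]
      ch[inside] <- body[c]
      img[, , c] <- ch
    }
    if (!is.null(m$sac)) {
      sin_ <- ((xs - m$sac$cx) / m$sac$r)^2 + ((ys - m$sac$cy) / m$sac$r)^2 <= 1
      for (c in 1:3) {
        ch <- img[, , c]
        ch[sin_] <- sac_col[c]
        img[, , c] <- ch
      }
    }
  }
  with_seed(layout$noise_seed, {
    if (night) {
      nz <- matrix(rnorm(H * W, 0, spec$noise_sd), H, W)
      for (c in 1:3) img[, , c] <- img[, , c] + nz   # grayscale-preserving
    } else if (spec$noise_sd > 0) {
      img <- img + array(rnorm(H * W * 3, 0, spec$noise_sd), c(H, W, 3L))
    }
  })
  img <- pmin(pmax(img, 0), 1)
  boxes <- if (length(layout$mares) == 0L) {
    tibble(x = numeric(), y = numeric(), w = numeric(), h = numeric())
  } else {
    bind_rows(lapply(layout$mares, function(m) {
      tibble(x = m$box[["x"]], y = m$box[["y"]], w = m$box[["w"]],
             h = m$box[["h"]])
    }))
  }
  structure(list(image = img, boxes = boxes,
                 labels = vapply(layout$mares, function(m) m$class,
                                 character(1)),
                 spec = spec),
            class = "synthetic_scene")
}

#' Generate a synthetic COCO dataset of stable scenes
#'
#' Draws `n_scenes` scenes from a spec template. Each scene is a
#' parturition (MP) scene independently with probability `mp_fraction`; in
#' an MP scene the first mare carries the fetal sac, all others are MNP.
#' Postures are drawn uniformly. With `out_dir` set, PNG images and a COCO
#' JSON (`annotations.json`) are written; with `render = FALSE` only the
#' record tables are built (no pixels), which is enough for bookkeeping
#' and sampling checks.
#'
#' @param n_scenes Number of scenes (>= 1).
#' @param mp_fraction Probability that a scene is a parturition scene.
#' @param spec_template A [scene_spec()] providing size, lighting, noise
#'   and mare count; its classes/postures/seed are redrawn per scene.
#' @param out_dir Output directory or `NULL`.
#' @param seed Integer seed for the whole dataset.
#' @param render Render pixel images (required when `out_dir` is set)?
#' @return A [coco_dataset()]; when rendering in memory the scenes are
#'   attached as attribute `"scenes"`.
#' @export
generate_dataset <- function(n_scenes, mp_fraction = 0.3,
                             spec_template = scene_spec(), out_dir = NULL,
                             seed = 1L, render = !is.null(out_dir)) {
  assert_that(is_count(n_scenes, 1L), "n_scenes must be >= 1")
  assert_that(is_prob(mp_fraction), "mp_fraction must be in [0, 1]")
  if (!is.null(out_dir)) {
    assert_that(render, "out_dir requires render = TRUE")
    ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE,
                                            showWarnings = FALSE)
    if (!ok || file.access(out_dir, 2L) != 0L) {
      abort(paste0("cannot write to out_dir: ", out_dir),
            class = "foalwatch_io_error")
    }
  }
  is_mp_scene <- with_seed(seed, runif(n_scenes) < mp_fraction)
  images <- vector("list", n_scenes)
  annos <- vector("list", n_scenes)
  scenes <- if (render && is.null(out_dir)) vector("list", n_scenes)
  ann_id <- 0L
  for (i in seq_len(n_scenes)) {
    n <- spec_template$n_mares
    postures <- with_seed(child_seed(seed, 2L * i), {
      sample(c("standing", "recumbent"), n, replace = TRUE)
    })
    classes <- rep("MNP", n)
    if (is_mp_scene[i] && n > 0L) classes[1L] <- "MP"
    spec_i <- scene_spec(spec_template$width, spec_template$height, n,
                         postures, classes, spec_template$lighting,
                         spec_template$noise_sd,
                         seed = child_seed(seed, 2L * i + 1L))
    file_name <- sprintf("scene_%05d.png", i)
    if (render) {
      sc <- generate_scene(spec_i)
      if (!is.null(out_dir)) {
        png::writePNG(fmap_to_png(sc$image), file.path(out_dir, file_name))
      } else {
        scenes[[i]] <- sc
      }
      boxes <- sc$boxes; labels <- sc$labels
    } else {
      layout <- scene_layout(spec_i)
      boxes <- bind_rows(lapply(layout$mares, function(m) {
        tibble(x = m$box[["x"]], y = m$box[["y"]], w = m$box[["w"]],
               h = m$box[["h"]])
      }))
      labels <- vapply(layout$mares, function(m) m$class, character(1))
    }
    images[[i]] <- tibble(id = i, file_name = file_name,
                          width = spec_template$width,
                          height = spec_template$height,
                          timestamp = NA_real_)
    if (n > 0L) {
      annos[[i]] <- tibble(id = ann_id + seq_len(n), image_id = i,
                           category_id = resolve_category(labels),
                           x = boxes$x, y = boxes$y, w = boxes$w,
                           h = boxes$h, area = boxes$w * boxes$h)
      ann_id <- ann_id + n
    }
  }
  ds <- coco_dataset(bind_rows(images),
                     if (length(annos)) bind_rows(annos) else
                       tibble(id = integer(), image_id = integer(),
                              category_id = integer(), x = numeric(),
                              y = numeric(), w = numeric(), h = numeric(),
                              area = numeric()))
  if (!is.null(out_dir)) {
    write_coco(ds, file.path(out_dir, "annotations.json"))
  }
  if (render && is.null(out_dir)) attr(ds, "scenes") <- scenes
  ds
}

# H x W x 3 array in [0,1] -> layout writePNG expects (same, but make sure
# values are clamped doubles).
fmap_to_png <- function(img) {
  pmin(pmax(img, 0), 1)
}

#' Specification of a simulated frame-label stream
#'
#' Emulates the per-second frame classifications a detector produces on a
#' monitoring video: before the parturition onset (or throughout, if there
#' is none) frames are labelled MP with probability `1 - specificity`; from
#' the onset on, with probability `sensitivity`.
#'
#' @param length_s Stream length in seconds.
#' @param onset_s True parturition onset (seconds from stream start), or
#'   `NULL` for a no-parturition video. Must satisfy
#'   `0 <= onset_s < length_s`.
#' @param sensitivity Per-frame probability of labelling a true MP frame MP.
#' @param specificity Per-frame probability of labelling a true MNP frame
#'   MNP.
#' @param seed Integer seed.
#' @return List of class `stream_spec`.
#' @export
stream_spec <- function(length_s, onset_s = NULL, sensitivity = 0.9,
                        specificity = 0.99, seed = 1L) {
  assert_that(is_count(length_s, 1L), "length_s must be a count >= 1")
  if (!is.null(onset_s)) {
    assert_that(onset_s >= 0 && onset_s < length_s,
                "onset_s must satisfy 0 <= onset_s < length_s")
  }
  assert_that(is_prob(sensitivity) && is_prob(specificity),
              "sensitivity and specificity must be probabilities")
  structure(list(length_s = as.integer(length_s), onset_s = onset_s,
                 sensitivity = sensitivity, specificity = specificity,
                 seed = seed),
            class = "stream_spec")
}

#' Simulate a per-second frame-label stream
#'
#' One label per second for `length_s` seconds (t = 0, 1, ...). Confidences
#' for the emitted label are Uniform(0.5, 1); downstream rules only use the
#' argmax label, so the exact confidence law is immaterial. Deterministic
#' per seed.
#'
#' @param spec A [stream_spec()].
#' @return Tibble `t, label, conf` with the true onset attached as
#'   attribute `"onset_s"` (NA when none).
#' @export
generate_stream <- function(spec) {
  n <- spec$length_s
  t <- seq_len(n) - 1L
  truth <- if (is.null(spec$onset_s)) rep(FALSE, n) else t >= spec$onset_s
  with_seed(spec$seed, {
    p_mp <- ifelse(truth, spec$sensitivity, 1 - spec$specificity)
    emitted_mp <- runif(n) < p_mp
    conf <- runif(n, 0.5, 1)
    out <- tibble(t = as.numeric(t),
                  label = ifelse(emitted_mp, "MP", "MNP"),
                  conf = conf)
    attr(out, "onset_s") <- if (is.null(spec$onset_s)) NA_real_ else
      spec$onset_s
    out
  })
}
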