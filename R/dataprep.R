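#' Select frames from a video's frame sequence
#'
#' Keeps one frame out of every `stride` (indices congruent to 0 modulo
#' `stride`, starting at frame 0) in temporal order, recording the source
#' timestamp `frame_index / fps`. The frame source is either a directory of
#' image files (sorted by name), a character vector of frame paths in
#' temporal order, or an integer frame count (records only). Decoding a
#' video container into frames is delegated to an external extractor; this
#' operation is the stride selection itself.
#'
#' @param frames Directory path, ordered character vector of frame paths,
#'   or a single integer frame count.
#' @param stride Keep every `stride`-th frame (>= 1; 10 by default).
#' @param fps Source frame rate used for timestamps (25).
#' @return Tibble of image records: `id`, `path`, `frame_index`,
#'   `timestamp`.
#' @export
extract_frames <- function(frames, stride = 10L, fps = 25) {
  assert_that(is_count(stride, 1L), "stride must be a count >= 1")
  if (is.numeric(frames) && length(frames) == 1L) {
    assert_that(is_count(frames, 0L), "frame count must be a count")
    paths <- sprintf("frame_%06d", seq_len(frames) - 1L)
  } else if (is.character(frames) && length(frames) == 1L) {
    if (!dir.exists(frames)) {
      abort(paste0("unreadable frame source: ", frames),
            class = "foalwatch_io_error")
    }
    paths <- sort(list.files(frames, full.names = TRUE))
  } else if (is.character(frames)) {
    paths <- frames
  } else {
    abort("frames must be a directory, paths, or a frame count",
          class = "foalwatch_io_error")
  }
  idx <- seq_along(paths) - 1L
  keep <- idx %% stride == 0L
  tibble(id = seq_len(sum(keep)), path = paths[keep],
         frame_index = idx[keep], timestamp = idx[keep] / fps)
}

#' Structural similarity (SSIM) of two grayscale images
#'
#' Local-window SSIM: means, variances and covariance are computed under a
#' sliding window (7 x 7 Gaussian with sigma 1.5 by default, or uniform),
#' combined as
#' `((2 ux uy + C1)(2 cov + C2)) / ((ux^2 + uy^2 + C1)(vx + vy + C2))`
#' with `C1 = (K1 L)^2`, `C2 = (K2 L)^2`, and averaged over the valid
#' (fully supported) region. Multichannel input is converted to luminance
#' first. `SSIM(x, x) == 1` for any image.
#'
#' @param a,b Matrices (or H x W x C arrays) of equal dims, values in
#'   `[0, data_range]`.
#' @param win_size Odd window size (7).
#' @param sigma Gaussian window SD (1.5); ignored for the uniform window.
#' @param K1,K2 Stability constants (0.01, 0.03).
#' @param data_range Intensity range L (1 for unit-scaled images).
#' @param window `"gaussian"` or `"uniform"`.
#' @param sample_covariance Use the n/(n-1) covariance correction (matches
#'   the common uniform-window reference); default `FALSE`.
#' @return SSIM index in `[-1, 1]`.
#' @export
ssim <- function(a, b, win_size = 7L, sigma = 1.5, K1 = 0.01, K2 = 0.03,
                 data_range = 1, window = c("gaussian", "uniform"),
                 sample_covariance = FALSE) {
  window <- match.arg(window)
  a <- to_gray(a); b <- to_gray(b)
  if (!all(dim(a) == dim(b))) {
    abort("images compared by SSIM must have identical dims",
          class = "foalwatch_contract_error")
  }
  assert_that(win_size %% 2L == 1L && win_size >= 3L,
              "win_size must be odd and >= 3")
  assert_that(all(dim(a) >= win_size), "images smaller than the window")
  kern <- if (window == "gaussian") {
    half <- (win_size - 1L) / 2
    g <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
    k <- outer(g, g)
    k / sum(k)
  } else {
    matrix(1 / win_size^2, win_size, win_size)
  }
  kf <- array(kern, c(win_size, win_size, 1L, 1L))
  filt <- function(m) conv2d(array(m, c(dim(m), 1L)), kf, pad = 0L)[, , 1L]
  ux <- filt(a); uy <- filt(b)
  uxx <- filt(a * a); uyy <- filt(b * b); uxy <- filt(a * b)
  cov_norm <- if (sample_covariance) win_size^2 / (win_size^2 - 1) else 1
  vx <- cov_norm * (uxx - ux * ux)
  vy <- cov_norm * (uyy - uy * uy)
  cxy <- cov_norm * (uxy - ux * uy)
  C1 <- (K1 * data_range)^2
  C2 <- (K2 * data_range)^2
  s <- ((2 * ux * uy + C1) * (2 * cxy + C2)) /
    ((ux^2 + uy^2 + C1) * (vx + vy + C2))
  mean(s)
}

to_gray <- function(x) {
  if (is.matrix(x)) return(x)
  x <- as_fmap(x)
  if (fmap_c(x) == 1L) return(x[, , 1L])
  0.2125 * x[, , 1L] + 0.7154 * x[, , 2L] + 0.0721 * x[, , 3L]
}

#' Sequential SSIM deduplication
#'
#' Walks an ordered image list and drops an image iff its SSIM to the LAST
#' RETAINED image strictly exceeds `threshold` (a pair at exactly the
#' threshold is kept). The first image is always retained and order is
#' preserved; the pass is idempotent. This sequential-greedy rule runs in
#' O(n) and targets redundancy between temporally adjacent frames.
#'
#' @param images List of matrices/arrays (equal dims) or PNG file paths.
#' @param threshold Similarity above which a frame is considered redundant
#'   (0.76).
#' @param ... Passed to [ssim()].
#' @return The retained images (same representation as the input), with
#'   the retained positions attached as attribute `"indices"`.
#' @export
dedup_ssim <- function(images, threshold = 0.76, ...) {
  assert_that(length(images) >= 1L, "images must be non-empty")
  load1 <- function(im) if (is.character(im)) png::readPNG(im) else im
  kept <- 1L
  last <- load1(images[[1L]])
  for (i in seq_along(images)[-1L]) {
    cur <- load1(images[[i]])
    if (ssim(cur, last, ...) <= threshold) {
      kept <- c(kept, i)
      last <- cur
    }
  }
  structure(images[kept], indices = kept)
}

#' Resize images (and scale boxes by the same factors)
#'
#' Bilinear resize to an exact target size; a 16:9 input resized to the
#' 384 x 216 working resolution keeps its aspect ratio (scale 0.2 on both
#' axes). Resizing to an image's own size is the identity.
#'
#' @param images A single image array or a list of them.
#' @param width,height Target size in pixels (384 x 216).
#' @return Same structure as the input, resized.
#' @export
resize_images <- function(images, width = 384L, height = 216L) {
  assert_that(width > 0 && height > 0, "target dims must be positive")
  single <- !is.list(images)
  if (single) images <- list(images)
  out <- lapply(images, function(im) {
    im <- as_fmap(im)
    if (fmap_h(im) == height && fmap_w(im) == width) im else
      bilinear_resize(im, height, width)
  })
  if (single) out[[1L]] else out
}

#' @rdname resize_images
#' @param boxes Tibble with `x, y, w, h` in source pixels.
#' @param fx,fy Scale factors (target / source) on x and y.
#' @export
scale_boxes <- function(boxes, fx, fy) {
  boxes$x <- boxes$x * fx; boxes$w <- boxes$w * fx
  boxes$y <- boxes$y * fy; boxes$h <- boxes$h * fy
  if ("area" %in% names(boxes)) boxes$area <- boxes$w * boxes$h
  boxes
}

#' Split configuration
#'
#' @param train_parts,test_parts Ratio parts (2:1 by default).
#' @param seed Shuffle seed.
#' @return List of class `split_config`.
#' @export
split_config <- function(train_parts = 2L, test_parts = 1L, seed = 1L) {
  assert_that(is_count(train_parts, 1L) && is_count(test_parts, 1L),
              "ratio parts must be counts >= 1")
  structure(list(train_parts = train_parts, test_parts = test_parts,
                 seed = seed),
            class = "split_config")
}

#' Random train/test split of a COCO dataset
#'
#' Shuffles images with the configured seed and takes the first
#' `round_half_up(n * train / (train + test))` as the training set - so a
#' 2:1 split of 5680 images yields 3787 train / 1893 test. The two parts
#' are disjoint and their union is the input; annotations follow their
#' images.
#'
#' @param dataset A [coco_dataset()].
#' @param config A [split_config()].
#' @return List with `train` and `test` datasets.
#' @export
split_dataset <- function(dataset, config = split_config()) {
  validate_coco(dataset)
  n <- nrow(dataset$images)
  assert_that(n >= 1L, "dataset must be non-empty")
  frac <- config$train_parts / (config$train_parts + config$test_parts)
  n_train <- floor(n * frac + 0.5)  # round half up on the train side
  perm <- with_seed(config$seed, sample.int(n))
  train_ids <- dataset$images$id[perm[seq_len(n_train)]]
  take <- function(ids) {
    coco_dataset(dataset$images[dataset$images$id %in% ids, , drop = FALSE],
                 dataset$annotations[dataset$annotations$image_id %in% ids, ,
                                     drop = FALSE],
                 dataset$categories)
  }
  list(train = take(train_ids),
       test = take(setdiff(dataset$images$id, train_ids)))
}

#' Augmentation configuration
#'
#' Random occlusion rectangles of 8-14 px a side (simulating small-object
#' occlusion at the 384 x 216 working resolution), contrast jitter with the
#' factor drawn from `1 + [0, contrast_limit]`, brightness jitter disabled
#' (limit 0), and Gaussian blur with strength in `[blur_low, blur_high]`.
#'
#' @param crop_h_min,crop_h_max,crop_w_min,crop_w_max Occlusion rectangle
#'   bounds in pixels.
#' @param brightness_limit Brightness jitter limit (0 = disabled).
#' @param contrast_limit Upper contrast jitter limit (factor 1 + U(0, c)).
#' @param blur_low,blur_high Blur strength (Gaussian sigma) bounds.
#' @param seed Integer seed.
#' @return List of class `augmentation_config`.
#' @export
augmentation_config <- function(crop_h_min = 8L, crop_h_max = 14L,
                                crop_w_min = 8L, crop_w_max = 14L,
                                brightness_limit = 0, contrast_limit = 1,
                                blur_low = 0.1, blur_high = 0.3, seed = 1L) {
  assert_that(crop_h_min <= crop_h_max && crop_w_min <= crop_w_max,
              "occlusion minima must not exceed maxima")
  assert_that(brightness_limit >= 0 && contrast_limit >= 0 &&
                blur_low >= 0 && blur_low <= blur_high,
              "augmentation limits must be nonnegative and ordered")
  structure(list(crop_h_min = as.integer(crop_h_min),
                 crop_h_max = as.integer(crop_h_max),
                 crop_w_min = as.integer(crop_w_min),
                 crop_w_max = as.integer(crop_w_max),
                 brightness_limit = brightness_limit,
                 contrast_limit = contrast_limit,
                 blur_low = blur_low, blur_high = blur_high, seed = seed),
            class = "augmentation_config")
}

#' Augment one image
#'
#' Applies the three augmentations (occlusion rectangle, contrast jitter,
#' light Gaussian blur) with parameters drawn from the config's ranges.
#' Deterministic per seed. The occluded rectangle's position is attached
#' as attribute `"occlusion"` (`x, y, w, h`, 0-based).
#'
#' @param image H x W x C array in `[0, 1]`.
#' @param config An [augmentation_config()].
#' @param seed Integer seed for this image's draws.
#' @return Augmented image array.
#' @export
augment_image <- function(image, config = augmentation_config(),
                          seed = config$seed) {
  img <- as_fmap(image)
  H <- fmap_h(img); W <- fmap_w(img)
  with_seed(seed, {
    oh <- sample(config$crop_h_min:config$crop_h_max, 1L)
    ow <- sample(config$crop_w_min:config$crop_w_max, 1L)
    oy <- sample.int(max(1L, H - oh + 1L), 1L)
    ox <- sample.int(max(1L, W - ow + 1L), 1L)
    contrast <- 1 + runif(1, 0, config$contrast_limit)
    brightness <- if (config$brightness_limit > 0) {
      runif(1, -config$brightness_limit, config$brightness_limit)
    } else 0
    blur_sigma <- runif(1, config$blur_low, config$blur_high)
    img[oy:(oy + oh - 1L), ox:(ox + ow - 1L), ] <- 0   # black occluder
    m <- mean(img)
    img <- m + (img - m) * contrast + brightness
    img <- pmin(pmax(img, 0), 1)
    img <- gaussian_blur(img, blur_sigma)
    attr(img, "occlusion") <- c(x = ox - 1L, y = oy - 1L, w = ow, h = oh)
    img
  })
}

gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  half <- max(1L, ceiling(2 * sigma))
  g <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  k <- outer(g, g); k <- k / sum(k)
  C <- fmap_c(img)
  kf <- array(0, c(nrow(k), ncol(k), C, C))
  for (c in seq_len(C)) kf[, , c, c] <- k
  out <- conv2d(img, kf, pad = "same")
  attributes(out) <- attributes(img)[c("dim")]
  out
}

#' Double a training set by augmentation
#'
#' Adds exactly one augmented copy of every image (new ids; annotations
#' duplicated onto the copy), so the output holds `2 n` images and exactly
#' twice the annotation count per class. When the dataset's images exist as
#' files under `image_dir`, pixels are augmented with [augment_image()] and
#' written as `*_aug.png`; a records-only dataset is doubled at the record
#' level.
#'
#' @param dataset Training [coco_dataset()].
#' @param config An [augmentation_config()].
#' @param image_dir Directory holding the dataset's image files, or `NULL`
#'   for a records-only pass.
#' @return Augmented [coco_dataset()].
#' @export
augment_dataset <- function(dataset, config = augmentation_config(),
                            image_dir = NULL) {
  validate_coco(dataset)
  n <- nrow(dataset$images)
  if (n == 0L) return(dataset)
  id_off <- max(dataset$images$id)
  ann_off <- if (nrow(dataset$annotations)) max(dataset$annotations$id) else 0L
  new_images <- dataset$images
  new_images$id <- new_images$id + id_off
  new_images$file_name <- sub("(\\.[a-zA-Z]+)?$", "_aug.png",
                              new_images$file_name)
  if (!is.null(image_dir)) {
    for (i in seq_len(n)) {
      src <- file.path(image_dir, dataset$images$file_name[i])
      assert_that(file.exists(src), paste0("missing image file: ", src))
      img <- png::readPNG(src)
      aug <- augment_image(img, config,
                           seed = child_seed(config$seed,
                                             dataset$images$id[i]))
      png::writePNG(fmap_to_png(aug),
                    file.path(image_dir, new_images$file_name[i]))
    }
  }
  new_ann <- dataset$annotations
  if (nrow(new_ann)) {
    new_ann$id <- new_ann$id + ann_off
    new_ann$image_id <- new_ann$image_id + id_off
  }
  coco_dataset(bind_rows(dataset$images, new_images),
               bind_rows(dataset$annotations, new_ann),
               dataset$categories)
}
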