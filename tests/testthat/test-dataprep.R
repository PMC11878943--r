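test_that("frame striding keeps every tenth frame with source timestamps", {
  rec <- extract_frames(95, stride = 10, fps = 25)
  expect_equal(nrow(rec), 10L)
  expect_equal(rec$frame_index, seq(0, 90, by = 10))
  # consecutive kept frames of a 25 fps source are 0.4 s apart
  expect_equal(diff(rec$timestamp), rep(0.4, 9))

  all_frames <- extract_frames(17, stride = 1)
  expect_equal(nrow(all_frames), 17L)

  expect_error(extract_frames(file.path(tempdir(), "no-such-dir")),
               "unreadable")
})

test_that("SSIM is 1 on identity and low on independent noise", {
  img <- withr::with_seed(1, matrix(runif(60 * 80), 60, 80))
  expect_equal(ssim(img, img), 1, tolerance = 1e-12)
  a <- withr::with_seed(2, matrix(runif(48 * 48), 48, 48))
  b <- withr::with_seed(3, matrix(runif(48 * 48), 48, 48))
  expect_lt(ssim(a, b), 0.3)
  expect_error(ssim(a, matrix(0, 10, 10)), "identical dims")
})

test_that("SSIM matches the scikit-image reference implementation", {
  a <- withr::with_seed(4, matrix(runif(40 * 50), 40, 50))
  b <- pmin(pmax(a + withr::with_seed(5, matrix(rnorm(40 * 50, 0, 0.1),
                                                40, 50)), 0), 1)
  dir <- withr::local_tempdir()
  write.table(a, file.path(dir, "a.csv"), row.names = FALSE,
              col.names = FALSE, sep = ",")
  write.table(b, file.path(dir, "b.csv"), row.names = FALSE,
              col.names = FALSE, sep = ",")
  script <- sprintf(
    "import numpy as np; from skimage.metrics import structural_similarity as s; a = np.loadtxt(r'%s', delimiter=','); b = np.loadtxt(r'%s', delimiter=','); print(float(s(a, b, win_size=7, data_range=1.0)))",
    file.path(dir, "a.csv"), file.path(dir, "b.csv"))
  ref <- as.numeric(system2("python", c("-c", shQuote(script)),
                            stdout = TRUE))
  ours <- ssim(a, b, window = "uniform", sample_covariance = TRUE)
  expect_equal(ours, ref, tolerance = 1e-6)
})

test_that("sequential dedup drops near-duplicates and is idempotent", {
  A <- withr::with_seed(6, matrix(runif(32 * 32), 32, 32))
  B <- withr::with_seed(7, matrix(runif(32 * 32), 32, 32))
  kept <- dedup_ssim(list(A, A, B), threshold = 0.76)
  expect_equal(attr(kept, "indices"), c(1L, 3L))

  # boundary: a pair at exactly the threshold is retained (strict >)
  s_ab <- ssim(A, B)
  kept2 <- dedup_ssim(list(A, B), threshold = s_ab)
  expect_equal(attr(kept2, "indices"), c(1L, 2L))

  # idempotence on a longer mixed sequence
  seq_imgs <- list(A, A, B, B, A)
  once <- dedup_ssim(seq_imgs)
  twice <- dedup_ssim(unclass(once))
  expect_equal(length(twice), length(once))
  expect_equal(attr(twice, "indices"), seq_along(once))
})

test_that("resizing hits the exact target and scales boxes linearly", {
  # full-size frame -> working resolution, aspect preserved (scale 0.2)
  big <- withr::with_seed(8, array(runif(1080 * 1920 * 3),
                                   c(1080, 1920, 3)))
  small <- resize_images(big, width = 384, height = 216)
  expect_equal(dim(small), c(216, 384, 3))

  # identity resize is pixel-exact
  img <- withr::with_seed(9, array(runif(40 * 60 * 3), c(40, 60, 3)))
  expect_identical(resize_images(img, width = 60, height = 40), img)

  boxes <- tibble::tibble(x = 100, y = 100, w = 500, h = 200)
  scaled <- scale_boxes(boxes, 0.2, 0.2)
  expect_equal(unlist(scaled), c(x = 20, y = 20, w = 100, h = 40))
})

test_that("the 2:1 split partitions the dataset with round-half-up", {
  ds <- records_dataset(5680)
  parts <- split_dataset(ds, split_config(seed = 1))
  expect_equal(nrow(parts$train$images), 3787L)
  expect_equal(nrow(parts$test$images), 1893L)
  expect_length(intersect(parts$train$images$id, parts$test$images$id), 0L)
  expect_setequal(c(parts$train$images$id, parts$test$images$id),
                  ds$images$id)

  small <- split_dataset(records_dataset(6), split_config(seed = 2))
  expect_equal(nrow(small$train$images), 4L)
  expect_equal(nrow(small$test$images), 2L)

  again <- split_dataset(ds, split_config(seed = 1))
  expect_identical(again$train$images$id, parts$train$images$id)
})

test_that("augmentation doubles images and per-class annotation counts", {
  ds <- records_dataset(101, labels = c("MP", "MNP", "MNP"))
  aug <- augment_dataset(ds)
  expect_equal(nrow(aug$images), 202L)
  before <- table(ds$annotations$category_id)
  after <- table(aug$annotations$category_id)
  expect_equal(as.vector(after), 2L * as.vector(before))

  empty <- coco_dataset(
    tibble::tibble(id = integer(), file_name = character(),
                   width = numeric(), height = numeric()),
    tibble::tibble(id = integer(), image_id = integer(),
                   category_id = integer(), x = numeric(), y = numeric(),
                   w = numeric(), h = numeric(), area = numeric()))
  expect_equal(nrow(augment_dataset(empty)$images), 0L)
})

test_that("pixel augmentation occludes a rectangle and is seeded", {
  img <- withr::with_seed(10, array(runif(60 * 90 * 3, 0.2, 1),
                                    c(60, 90, 3)))
  aug <- augment_image(img, augmentation_config(seed = 3))
  occ <- attr(aug, "occlusion")
  expect_true(occ[["w"]] >= 8 && occ[["w"]] <= 14)
  expect_true(occ[["h"]] >= 8 && occ[["h"]] <= 14)
  patch <- img[occ[["y"]] + seq_len(occ[["h"]]),
               occ[["x"]] + seq_len(occ[["w"]]), ]
  aug_patch <- aug[occ[["y"]] + seq_len(occ[["h"]]),
                   occ[["x"]] + seq_len(occ[["w"]]), ]
  expect_false(isTRUE(all.equal(patch, aug_patch)))
  expect_identical(augment_image(img, augmentation_config(seed = 3)),
                   aug)
})

test_that("file-backed augmentation writes one augmented copy per image", {
  dir <- withr::local_tempdir()
  ds <- generate_dataset(2, mp_fraction = 1,
                         spec_template = scene_spec(n_mares = 1,
                                                    width = 96, height = 64),
                         out_dir = dir, seed = 5)
  aug <- augment_dataset(ds, augmentation_config(seed = 6), image_dir = dir)
  expect_equal(nrow(aug$images), 4L)
  expect_length(list.files(dir, pattern = "_aug\\.png$"), 2L)
})

test_that("COCO I/O round-trips and validates referential integrity", {
  ds <- records_dataset(4)
  path <- withr::local_tempfile(fileext = ".json")
  write_coco(ds, path)
  back <- read_coco(path)
  expect_equal(back$images[, c("id", "file_name", "width", "height")],
               ds$images[, c("id", "file_name", "width", "height")])
  expect_equal(back$annotations, ds$annotations, tolerance = 1e-12)

  bad_ann <- ds$annotations
  bad_ann$image_id[2] <- 999L
  expect_error(coco_dataset(ds$images, bad_ann), "missing image")

  oob <- ds$annotations
  oob$w[1] <- 1e5
  oob$area[1] <- oob$w[1] * oob$h[1]
  expect_error(coco_dataset(ds$images, oob), "out-of-bounds")

  bad_json <- withr::local_tempfile(fileext = ".json")
  writeLines("{not json", bad_json)
  expect_error(read_coco(bad_json), "malformed")
})
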