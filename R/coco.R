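#' COCO-style detection dataset
#'
#' A lightweight container mirroring the COCO JSON layout: an `images`
#' tibble (`id`, `file_name`, `width`, `height`, optional `timestamp`), an
#' `annotations` tibble (`id`, `image_id`, `category_id`, `x`, `y`, `w`,
#' `h`, `area`) and a `categories` tibble (MP = 1, MNP = 2). Boxes are
#' absolute pixels, 0-based, top-left origin.
#'
#' @param images,annotations,categories Tibbles as described above.
#' @return A validated `coco_dataset`.
#' @export
coco_dataset <- function(images, annotations,
                         categories = canonical_categories()) {
  ds <- structure(list(images = as_tibble(images),
                       annotations = as_tibble(annotations),
                       categories = as_tibble(categories)),
                  class = "coco_dataset")
  validate_coco(ds)
}

validate_coco <- function(ds) {
  im <- ds$images; an <- ds$annotations
  assert_that(all(c("id", "file_name", "width", "height") %in% names(im)),
              "images table needs id, file_name, width, height")
  assert_that(!anyDuplicated(im$id), "image ids must be unique")
  assert_that(all(im$width > 0) && all(im$height > 0),
              "image dims must be positive")
  needed <- c("id", "image_id", "category_id", "x", "y", "w", "h", "area")
  assert_that(all(needed %in% names(an)),
              paste("annotations table needs:", paste(needed, collapse = ", ")))
  if (nrow(an) > 0L) {
    assert_that(!anyDuplicated(an$id), "annotation ids must be unique")
    dangling <- setdiff(an$image_id, im$id)
    if (length(dangling) > 0L) {
      bad <- an$id[an$image_id %in% dangling]
      abort(sprintf("annotation(s) %s reference missing image(s) %s",
                    paste(bad, collapse = ", "),
                    paste(dangling, collapse = ", ")),
            class = "foalwatch_validation_error")
    }
    idx <- match(an$image_id, im$id)
    oob <- an$x < 0 | an$y < 0 |
      an$x + an$w > im$width[idx] + 1e-6 |
      an$y + an$h > im$height[idx] + 1e-6
    if (any(oob)) {
      abort(sprintf("annotation(s) %s have out-of-bounds boxes",
                    paste(an$id[oob], collapse = ", ")),
            class = "foalwatch_validation_error")
    }
    assert_that(all(abs(an$area - an$w * an$h) < 1e-6),
                "annotation area must equal w * h")
    assert_that(all(an$category_id %in% ds$categories$id),
                "annotation category not in categories table")
  }
  ds
}

#' @export
print.coco_dataset <- function(x, ...) {
  cat(sprintf("<coco_dataset: %d images, %d annotations, %d categories>\n",
              nrow(x$images), nrow(x$annotations), nrow(x$categories)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.coco_dataset <- function(x, ...) {
  an <- x$annotations
  an$label <- x$categories$name[match(an$category_id, x$categories$id)]
  an
}

#' @exportS3Method generics::glance
glance.coco_dataset <- function(x, ...) {
  lab <- tidy(x)
  tibble(n_images = nrow(x$images),
         n_annotations = nrow(x$annotations),
         n_mp = sum(lab$label == "MP"),
         n_mnp = sum(lab$label == "MNP"))
}

#' Write a dataset as COCO JSON
#'
#' @param dataset A [coco_dataset()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_coco <- function(dataset, path) {
  validate_coco(dataset)
  im <- dataset$images
  images <- lapply(seq_len(nrow(im)), function(i) {
    rec <- list(id = im$id[i], file_name = im$file_name[i],
                width = im$width[i], height = im$height[i])
    if ("timestamp" %in% names(im) && !is.na(im$timestamp[i])) {
      rec$timestamp <- im$timestamp[i]
    }
    rec
  })
  an <- dataset$annotations
  annotations <- lapply(seq_len(nrow(an)), function(i) {
    list(id = an$id[i], image_id = an$image_id[i],
         category_id = an$category_id[i],
         bbox = c(an$x[i], an$y[i], an$w[i], an$h[i]),
         area = an$area[i], iscrowd = 0L)
  })
  categories <- lapply(seq_len(nrow(dataset$categories)), function(i) {
    list(id = dataset$categories$id[i], name = dataset$categories$name[i])
  })
  jsonlite::write_json(
    list(images = images, annotations = annotations,
         categories = categories),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a COCO JSON file
#'
#' Validates referential integrity (every annotation must reference an
#' existing image), box bounds and the `area == w * h` identity; violations
#' raise an error naming the offending record.
#'
#' @param path COCO JSON file path.
#' @return A [coco_dataset()].
#' @export
read_coco <- function(path) {
  assert_that(file.exists(path), paste0("no such file: ", path))
  raw <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) {
                    abort(paste0("malformed COCO JSON: ", conditionMessage(e)),
                          class = "foalwatch_validation_error")
                  })
  images <- bind_rows(lapply(raw$images, function(r) {
    tibble(id = as.integer(r$id), file_name = as.character(r$file_name),
           width = as.numeric(r$width), height = as.numeric(r$height),
           timestamp = if (is.null(r$timestamp)) NA_real_ else
             as.numeric(r$timestamp))
  }))
  annotations <- if (length(raw$annotations) == 0L) {
    tibble(id = integer(), image_id = integer(), category_id = integer(),
           x = numeric(), y = numeric(), w = numeric(), h = numeric(),
           area = numeric())
  } else {
    bind_rows(lapply(raw$annotations, function(r) {
      bbox <- as.numeric(unlist(r$bbox))
      tibble(id = as.integer(r$id), image_id = as.integer(r$image_id),
             category_id = as.integer(r$category_id),
             x = bbox[1], y = bbox[2], w = bbox[3], h = bbox[4],
             area = as.numeric(r$area))
    }))
  }
  categories <- bind_rows(lapply(raw$categories, function(r) {
    tibble(id = as.integer(r$id), name = as.character(r$name))
  }))
  coco_dataset(images, annotations, categories)
}
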