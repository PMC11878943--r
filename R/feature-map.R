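#' Feature maps
#'
#' A feature map is a plain numeric array with dimensions height x width x
#' channels (H x W x C). All neural operators in the package consume and
#' produce this layout; a matrix is treated as a single-channel map.
#'
#' @param x A numeric array (H x W x C), matrix (H x W) or 3-d array.
#' @return A numeric H x W x C array.
#' @examples
#' fm <- as_fmap(matrix(1:12, 3, 4))
#' dim(fm) # 3 4 1
#' @export
as_fmap <- function(x) {
  if (is.matrix(x)) x <- array(x, c(dim(x), 1L))
  assert_that(is.array(x) && length(dim(x)) == 3L,
              "a feature map must be an H x W x C array")
  assert_that(all(is.finite(x)), "feature map entries must be finite")
  assert_that(all(dim(x) >= 1L), "feature map dims must be >= 1")
  storage.mode(x) <- "double"
  x
}

fmap_h <- function(x) dim(x)[1L]
fmap_w <- function(x) dim(x)[2L]
fmap_c <- function(x) dim(x)[3L]
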