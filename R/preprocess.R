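#' Standardize a fundus-style image
#'
#' The standard intensity pipeline: RGB is converted to grayscale with
#' luminance weights (0.299, 0.587, 0.114), the image is z-scored (zero mean,
#' unit variance over all pixels) and then linearly rescaled so its minimum
#' maps to 0 and its maximum to 255. A constant input cannot be z-scored; it
#' is returned as mid-gray (127.5 everywhere) with attribute
#' `degenerate = TRUE` and a warning.
#'
#' @param image `H x W` numeric matrix or `H x W x 3` RGB array, any scale.
#' @return `H x W` matrix spanning `[0, 255]` (attribute `degenerate` set for
#'   constant inputs).
#' @export
standardizeImage <- function(image) {
  if (length(dim(image)) == 3L) {
    if (dim(image)[3] == 3L)
      image <- 0.299 * image[, , 1] + 0.587 * image[, , 2] +
        0.114 * image[, , 3]
    else image <- image[, , 1]
  }
  s <- stats::sd(image)
  if (!is.finite(s) || s == 0) {
    warning("constant image cannot be standardized; returning mid-gray")
    out <- matrix(127.5, nrow(image), ncol(image))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  z <- (image - mean(image)) / s
  out <- (z - min(z)) / (max(z) - min(z)) * 255
  attr(out, "degenerate") <- FALSE
  out
}

#' Contrast-limited adaptive histogram equalization
#'
#' Tile-wise histogram equalization with clipping and bilinear tile blending
#' (delegated to EBImage's CLAHE), applied on the `[0, 255]` scale. A
#' constant image has no contrast to redistribute and is returned unchanged.
#'
#' @param image `H x W` matrix in `[0, 255]`.
#' @param clipLimit contrast clip limit (default 2).
#' @param tileGrid number of tiles along each axis (default 8).
#' @return equalized `H x W` matrix in `[0, 255]`.
#' @export
claheEnhance <- function(image, clipLimit = 2, tileGrid = 8L) {
  if (tileGrid > nrow(image) || tileGrid > ncol(image))
    stop("tile grid larger than the image")
  if (max(image) - min(image) < .Machine$double.eps * 255)
    return(image)
  y <- EBImage::clahe(image / 255, nx = tileGrid, ny = tileGrid,
                      limit = clipLimit, keep.range = TRUE)
  matrix(pmin(pmax(as.numeric(y), 0), 1) * 255, nrow(image), ncol(image))
}

rot90cw <- function(m) t(m[nrow(m):1, , drop = FALSE])

applyD4 <- function(m, k, flip) {
  if (flip) m <- m[, ncol(m):1, drop = FALSE]
  for (i in seq_len(k)) m <- rot90cw(m)
  m
}

#' Eightfold dihedral augmentation
#'
#' Applies the eight symmetries of the square (the dihedral group D4: four
#' rotations by 0/90/180/270 degrees, each with and without a horizontal
#' flip) to an image/mask record. The vertical flip is contained in the
#' group as horizontal flip + 180-degree rotation, so "axial flips plus four
#' rotations" yields exactly eight distinct transforms. Image and mask are
#' transformed identically, preserving their alignment and the vessel pixel
#' count.
#'
#' @param record a list with `image` and `mask` (`H x W` matrices, square),
#'   optionally `id`; a bare matrix is treated as an image with no mask.
#' @return a list of exactly 8 records; ids gain suffixes
#'   `_r{0,90,180,270}` and `_hf` for the flipped set.
#' @export
augment8 <- function(record) {
  if (is.matrix(record)) record <- list(image = record, mask = NULL)
  img <- record$image
  if (nrow(img) != ncol(img))
    stop("augment8 requires square images (90-degree rotations must ",
         "preserve the shape)")
  out <- vector("list", 8L)
  i <- 1L
  for (flip in c(FALSE, TRUE))
    for (k in 0:3) {
      r <- record
      r$image <- applyD4(img, k, flip)
      if (!is.null(record$mask)) r$mask <- applyD4(record$mask, k, flip)
      suffix <- paste0("_r", k * 90L, if (flip) "_hf" else "")
      r$id <- paste0(record$id %||% "img", suffix)
      out[[i]] <- r
      i <- i + 1L
    }
  out
}

#' Full preprocessing of a record
#'
#' Grayscale conversion, z-score standardization with rescale to `[0, 255]`,
#' then CLAHE — the order of the standard pipeline.
#'
#' @param record list with `image` (and optionally `mask`).
#' @param clipLimit,tileGrid CLAHE settings (see [claheEnhance()]).
#' @return the record with `image` replaced by its preprocessed version.
#' @export
preprocessRecord <- function(record, clipLimit = 2, tileGrid = 8L) {
  img <- standardizeImage(record$image)
  deg <- isTRUE(attr(img, "degenerate"))
  if (!deg) img <- claheEnhance(img, clipLimit, tileGrid)
  record$image <- img
  record$degenerate <- deg
  record
}
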