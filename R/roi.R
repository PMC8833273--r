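#' Circular region of interest with an exact pixel count
#'
#' @param center numeric (row, col) center in pixel coordinates.
#' @param pixelCount exact number of pixels the ROI must contain.
#' @return an [ROISpec-class] of circular kind.
#'
#' @examples
#' circularROI(c(64.5, 64.5), 52)
#' @seealso [resolveROI()]
#' @export
circularROI <- function(center, pixelCount) {
  new("ROISpec", kind = "circular", center = as.numeric(center),
      targetPixelCount = as.integer(pixelCount),
      pixels = matrix(integer(), 0, 2))
}

#' Explicit pixel-mask region of interest
#'
#' @param pixels two-column integer matrix of (row, col) coordinates.
#' @return an [ROISpec-class] of mask kind.
#'
#' @examples
#' maskROI(cbind(3:5, 4))
#' @seealso [resolveROI()]
#' @export
maskROI <- function(pixels) {
  px <- as.matrix(pixels)
  storage.mode(px) <- "integer"
  colnames(px) <- c("row", "col")
  new("ROISpec", kind = "mask", center = numeric(), targetPixelCount = NA_integer_,
      pixels = px)
}

#' Resolve an ROI to a concrete pixel set
#'
#' For a circular ROI, returns exactly `targetPixelCount` pixels: the grid
#' pixels nearest the center in Euclidean distance, ties broken
#' deterministically in row-major order, so the published ROI sizes (e.g.
#' 52 or 1264 pixels) are met exactly. For a mask ROI the stored pixels are
#' bounds-checked and returned. Pixels are returned sorted in row-major
#' order.
#'
#' @param roi an [ROISpec-class].
#' @param imageShape integer (rows, cols) of the target image.
#' @return two-column integer matrix of (row, col) coordinates.
#'
#' @examples
#' nrow(resolveROI(circularROI(c(64, 64), 52), c(128, 128)))  # 52
#' @export
resolveROI <- function(roi, imageShape) {
  stopifnot(is(roi, "ROISpec"))
  validObject(roi)
  shape <- as.integer(imageShape)
  if (length(shape) != 2L || any(shape < 1L))
    stop("imageShape must be two positive integers", call. = FALSE)
  if (roi@kind == "mask") {
    px <- roi@pixels
    if (any(px[, 1] > shape[1]) || any(px[, 2] > shape[2]))
      stop("mask pixels out of image bounds", call. = FALSE)
    ord <- order((px[, 1] - 1L) * shape[2] + px[, 2])
    px <- px[ord, , drop = FALSE]
    if (anyDuplicated(px)) stop("mask pixels must be unique", call. = FALSE)
    return(px)
  }
  k <- roi@targetPixelCount
  if (k > prod(shape))
    stop("targetPixelCount exceeds the number of image pixels", call. = FALSE)
  ctr <- roi@center
  if (ctr[1] < 1 || ctr[1] > shape[1] || ctr[2] < 1 || ctr[2] > shape[2])
    stop("ROI center lies outside the image", call. = FALSE)
  rr <- rep(seq_len(shape[1]), times = shape[2])
  cc <- rep(seq_len(shape[2]), each = shape[1])
  d2 <- (rr - ctr[1])^2 + (cc - ctr[2])^2
  rowMajor <- (rr - 1L) * shape[2] + cc
  sel <- order(d2, rowMajor)[seq_len(k)]
  px <- cbind(row = rr[sel], col = cc[sel])
  px[order(rowMajor[sel]), , drop = FALSE]
}

## pixel values of an image over a resolved ROI, in row-major order
.roiValues <- function(img, px) {
  pixels(img)[cbind(px[, 1], px[, 2])]
}
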