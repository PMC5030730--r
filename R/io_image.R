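# Frame and label-map I/O. Frames are held internally as numeric matrices
# indexed [row, col] with intensities in [0, 1]; EBImage stores (x, y), hence
# the transposes at the boundary.

#' Read a gray-scale frame from disk
#'
#' Reads an 8/16-bit TIFF or 8-bit PNG and returns a numeric `[row, col]`
#' matrix with intensities in `[0, 1]`. Multi-channel images are averaged to
#' one gray channel.
#'
#' @param path image file path.
#' @return numeric matrix in `[0, 1]`.
#' @export
read_frame <- function(path) {
  if (!file.exists(path)) stopf("frame not found: %s", path)
  img <- EBImage::readImage(path)
  d <- EBImage::imageData(img)
  if (length(dim(d)) == 3L) d <- apply(d, c(1L, 2L), mean)
  t(d)
}

#' Write a gray-scale frame to disk
#'
#' @param image numeric `[row, col]` matrix in `[0, 1]`.
#' @param path destination; format chosen by extension (.tif/.tiff/.png).
#' @param bits bits per sample for TIFF (8 or 16; default 16).
#' @export
write_frame <- function(image, path, bits = 16L) {
  ext <- tolower(tools::file_ext(path))
  img <- EBImage::Image(t(pmin(pmax(image, 0), 1)))
  if (ext %in% c("tif", "tiff")) {
    EBImage::writeImage(img, path, type = "tiff", bits.per.sample = as.integer(bits))
  } else if (ext == "png") {
    EBImage::writeImage(img, path, type = "png")
  } else {
    stopf("unsupported image extension: .%s", ext)
  }
  invisible(path)
}

#' Write a label map as a 16-bit TIFF
#'
#' Labels are stored as `label / 65535` so that `read_label_map()` recovers
#' them exactly for up to 65535 objects per frame.
#'
#' @param labels integer LabelMap matrix.
#' @param path destination path (.tif/.tiff).
#' @export
write_label_map <- function(labels, path) {
  if (max(labels) > 65535L) stopf("more than 65535 labels cannot be stored in 16-bit TIFF")
  img <- EBImage::Image(t(labels / 65535))
  EBImage::writeImage(img, path, type = "tiff", bits.per.sample = 16L)
  invisible(path)
}

#' Read a label map written by [write_label_map()]
#'
#' @param path TIFF path.
#' @return integer LabelMap matrix.
#' @export
read_label_map <- function(path) {
  m <- read_frame(path)
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}

#' Write an outline overlay PNG
#'
#' Renders the (normalized) frame with object boundary pixels painted, the
#' usual visual QC artifact for segmentation runs.
#'
#' @param image numeric frame in `[0, 1]`.
#' @param labels LabelMap of the same shape.
#' @param path destination PNG path.
#' @param col outline colour (default red).
#' @export
write_outline_overlay <- function(image, labels, path, col = "red") {
  img <- EBImage::rgbImage(red = t(image), green = t(image), blue = t(image))
  lab <- EBImage::Image(t(labels))
  over <- EBImage::paintObjects(lab, img, col = col)
  EBImage::writeImage(over, path, type = "png")
  invisible(path)
}
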