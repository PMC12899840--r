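# Binary masks are plain integer matrices with entries in {0, 1},
# row-major pixel bookkeeping: 0-based (row, col), origin top-left.

#' Validate a binary mask
#'
#' @param mask matrix; every entry must be 0 or 1.
#' @param arg name used in error messages.
#' @return the mask, invisibly, as an integer matrix.
#' @keywords internal
check_mask <- function(mask, arg = "mask") {
  if (!is.matrix(mask)) stop(sprintf("`%s` must be a matrix", arg))
  if (nrow(mask) < 1L || ncol(mask) < 1L)
    stop(sprintf("`%s` must have at least one row and one column", arg))
  if (anyNA(mask) || !all(mask == 0L | mask == 1L))
    stop(sprintf("`%s` must contain only 0 and 1", arg))
  storage.mode(mask) <- "integer"
  invisible(mask)
}

#' Load a binary plant mask from a PNG file
#'
#' Decodes an 8-bit grayscale or RGB PNG and thresholds it into a 0/1 mask.
#' A pixel is foreground when its decoded intensity exceeds
#' `foreground_threshold`; for RGB input a pixel is foreground when any
#' channel exceeds the threshold. Alpha channels are ignored.
#'
#' @param path path to a PNG file.
#' @param foreground_threshold intensity on the 0--255 scale; pixels strictly
#'   above it are foreground. Default 0, i.e. any nonzero pixel is plant.
#' @return integer matrix of 0/1 (rows x cols).
#' @export
#' @examples
#' f <- tempfile(fileext = ".png")
#' write_mask(matrix(c(0L, 1L, 1L, 0L), 2, 2), f)
#' load_mask(f)
load_mask <- function(path, foreground_threshold = 0) {
  if (!file.exists(path)) stop("cannot read mask, file does not exist: ", path)
  px <- tryCatch(png::readPNG(path), error = function(e)
    stop("failed to decode PNG ", path, ": ", conditionMessage(e)))
  px <- px * 255
  if (length(dim(px)) == 3L) {
    nch <- dim(px)[3L]
    if (nch >= 3L) px <- px[, , 1:3, drop = FALSE] # drop alpha
    m <- apply(px > foreground_threshold, c(1L, 2L), any)
  } else {
    m <- px > foreground_threshold
  }
  if (nrow(m) < 1L || ncol(m) < 1L) stop("zero-size image: ", path)
  mode(m) <- "integer"
  m
}

#' Write a binary mask to an 8-bit grayscale PNG
#'
#' Foreground pixels are written as 255, background as 0, so the file
#' round-trips exactly through [load_mask()].
#'
#' @param mask 0/1 matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  mask <- check_mask(mask)
  png::writePNG(mask * 1.0, path)
  invisible(path)
}

#' Load a single-channel intensity image
#'
#' Decodes a PNG on the 0--255 scale. RGB images are reduced to one channel:
#' by default ITU-R BT.601 luminance (0.299 R + 0.587 G + 0.114 B), or a
#' single band when `band` is given.
#'
#' @param path path to a PNG file.
#' @param band `NULL` for luminance, or one of `"r"`, `"g"`, `"b"`.
#' @return numeric matrix with values in \[0, 255\].
#' @export
load_intensity <- function(path, band = NULL) {
  if (!file.exists(path)) stop("cannot read image, file does not exist: ", path)
  px <- tryCatch(png::readPNG(path), error = function(e)
    stop("failed to decode PNG ", path, ": ", conditionMessage(e)))
  px <- px * 255
  d <- dim(px)
  if (length(d) == 3L) {
    if (is.null(band)) {
      px <- 0.299 * px[, , 1L] + 0.587 * px[, , 2L] + 0.114 * px[, , 3L]
    } else {
      i <- match(match.arg(band, c("r", "g", "b")), c("r", "g", "b"))
      px <- px[, , i]
    }
    if (!is.matrix(px)) px <- matrix(px, d[1L], d[2L]) # 1-pixel edge case
  }
  if (nrow(px) < 1L || ncol(px) < 1L) stop("zero-size image: ", path)
  px
}

#' Write an intensity image to an 8-bit grayscale PNG
#'
#' @param image numeric matrix with values in \[0, 255\].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_intensity <- function(image, path) {
  stopifnot(is.matrix(image), all(image >= 0), all(image <= 255))
  png::writePNG(round(image) / 255, path)
  invisible(path)
}
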