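#' Chamber image container
#'
#' A `chamber_image` couples a single-channel grayscale raster with its
#' physical calibration (micrometres per pixel edge). Intensities are
#' rescaled to `[0, 1]` on construction by dividing by the inferred bit
#' depth maximum (255 for 8-bit, 4095 for 12-bit, 65535 for 16-bit data);
#' data already in `[0, 1]` are left unchanged.
#'
#' @param pixels numeric matrix of non-negative, finite intensities, at
#'   least 2 x 2. Rows are image rows (y), columns are image columns (x).
#' @param pixel_size physical edge length of one pixel, micrometres (> 0).
#'
#' @return An object of class `chamber_image`: a list with elements
#'   `pixels` (matrix in `[0, 1]`) and `pixel_size`.
#' @export
#' @examples
#' img <- chamber_image(matrix(runif(100), 10), pixel_size = 0.5)
#' dim(img$pixels)
chamber_image <- function(pixels, pixel_size) {
  pixels <- as.matrix(pixels)
  storage.mode(pixels) <- "double"
  if (nrow(pixels) < 2 || ncol(pixels) < 2)
    stop("chamber_image: pixels must have at least 2 rows and 2 columns")
  if (!all(is.finite(pixels)) || any(pixels < 0))
    stop("chamber_image: intensities must be finite and non-negative")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1 ||
      !is.finite(pixel_size) || pixel_size <= 0)
    stop("chamber_image: pixel_size must be a single positive number")
  mx <- max(pixels)
  if (mx > 1) {
    depth_max <- if (mx <= 255) 255 else if (mx <= 4095) 4095 else 65535
    pixels <- pixels / depth_max
  }
  structure(list(pixels = pixels, pixel_size = as.numeric(pixel_size)),
            class = "chamber_image")
}

#' @export
print.chamber_image <- function(x, ...) {
  cat(sprintf("<chamber_image> %d x %d px, %.4g um/px, intensity [%.3f, %.3f]\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Binary mask container
#'
#' @param pixels logical matrix, same shape as the source image.
#' @param provenance short tag naming the operation that produced the mask.
#' @return An object of class `binary_mask` with elements `pixels` and
#'   `provenance`.
#' @export
binary_mask <- function(pixels, provenance = "unknown") {
  pixels <- as.matrix(pixels)
  if (!is.logical(pixels)) {
    if (!all(pixels %in% c(0, 1, NA)))
      stop("binary_mask: pixels must be logical or 0/1")
    pixels <- pixels > 0
  }
  structure(list(pixels = pixels, provenance = as.character(provenance)),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d px, %d foreground [%s]\n",
              nrow(x$pixels), ncol(x$pixels), sum(x$pixels), x$provenance))
  invisible(x)
}

as_mask_matrix <- function(x) {
  if (inherits(x, "binary_mask")) x$pixels else {
    m <- as.matrix(x)
    if (!is.logical(m)) m <- m > 0
    m
  }
}

as_image_matrix <- function(x) {
  if (inherits(x, "chamber_image")) x$pixels else as.matrix(x)
}

#' Read a chamber image from a TIFF or PNG file
#'
#' Reads a single-channel grayscale image. Multi-channel files are rejected
#' unless `channel` selects one plane. Intensities are normalized to
#' `[0, 1]` (both readers already return this range).
#'
#' @param path path to a `.tif`/`.tiff` or `.png` file.
#' @param pixel_size physical pixel size, micrometres per pixel.
#' @param channel optional channel index for multi-channel files.
#' @return A [chamber_image()].
#' @export
read_chamber_image <- function(path, pixel_size, channel = NULL) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image format: ", ext, " (use TIFF or PNG)")
  )
  if (length(dim(raw)) == 3) {
    if (is.null(channel))
      stop("multi-channel image; supply `channel` to select one plane")
    if (channel < 1 || channel > dim(raw)[3])
      stop("channel index out of range")
    raw <- raw[, , channel]
  }
  chamber_image(raw, pixel_size)
}

#' Write a binary mask as a PNG file
#'
#' Foreground pixels are written as 255, background as 0.
#'
#' @param mask a [binary_mask()] or logical matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  m <- as_mask_matrix(mask)
  png::writePNG(m * 1.0, path)
  invisible(path)
}
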