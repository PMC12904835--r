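#' Construct a gel image object
#'
#' @param pixels numeric matrix of grey values in [0,1], rows = image rows
#'   (top to bottom), columns = image columns.
#' @param polarity `"bands_bright"` (always, after auto-inversion) or
#'   `"bands_dark"`.
#' @return object of class `gel_image` with fields `pixels`, `height`,
#'   `width`, `polarity`.
#' @export
gel_image <- function(pixels, polarity = c("bands_bright", "bands_dark")) {
  polarity <- match.arg(polarity)
  pixels <- as.matrix(pixels)
  if (nrow(pixels) < 16L || ncol(pixels) < 16L)
    validation_error("gel image too small (%dx%d); need at least 16x16",
                     nrow(pixels), ncol(pixels))
  if (min(pixels) < 0 || max(pixels) > 1)
    validation_error("gel image grey values must lie in [0,1]")
  structure(list(pixels = pixels, height = nrow(pixels),
                 width = ncol(pixels), polarity = polarity),
            class = "gel_image")
}

#' @export
print.gel_image <- function(x, ...) {
  cat(sprintf("<gel_image> %dx%d px, %s\n", x$height, x$width, x$polarity))
  invisible(x)
}

#' Load and standardize a gel electrophoresis image
#'
#' Reads a PNG/JPG/JPEG, converts to grayscale, applies a mild Gaussian blur
#' (sigma = `blur_sigma` px, suppressing compression noise ahead of
#' thresholding), and standardizes polarity so that DNA bands are always
#' bright on a dark background. Polarity is auto-detected from the Otsu
#' threshold of the blurred image: bands occupy a minority of pixels, so if
#' the above-threshold (bright) class is the majority the bands must be dark
#' and the image is inverted.
#'
#' @param path image file path.
#' @param blur_sigma Gaussian blur sigma in px (default 1).
#' @return a [gel_image()] with `polarity = "bands_bright"`.
#' @export
load_gel_image <- function(path, blur_sigma = 1) {
  if (!file.exists(path)) io_error("image file not found: %s", path)
  img <- tryCatch(suppressWarnings(EBImage::readImage(path)),
                  error = function(e) io_error("cannot read image %s: %s",
                                               path, conditionMessage(e)))
  if (EBImage::colorMode(img) == EBImage::Color)
    img <- EBImage::channel(img, "gray")
  d <- dim(img)
  if (length(d) > 2L) img <- EBImage::Image(EBImage::imageData(img)[, , 1])
  if (d[1] < 16L || d[2] < 16L)
    validation_error("gel image too small (%dx%d); need at least 16x16",
                     d[2], d[1])
  px <- EBImage::imageData(img)
  px <- pmin(pmax(px, 0), 1)
  if (blur_sigma > 0) {
    img <- EBImage::gblur(EBImage::Image(px), sigma = blur_sigma)
    px <- pmin(pmax(EBImage::imageData(img), 0), 1)
  }
  thr <- EBImage::otsu(EBImage::Image(px))
  if (mean(px > thr) > 0.5) px <- 1 - px  # bright class is majority: bands are dark
  # EBImage stores x (columns) first; transpose to rows = image rows
  gel_image(t(px), polarity = "bands_bright")
}

#' Detect vertical DNA lanes
#'
#' Otsu-thresholds the column-wise mean intensity profile to separate lane
#' columns from background; contiguous above-threshold runs at least
#' `min_width` columns wide become lanes, ordered left to right, each with
#' its center column.
#'
#' @param img a [gel_image()] (bands bright).
#' @param min_width minimum lane width in columns; default 1% of image width,
#'   at least 2, to reject specks.
#' @return object of class `lane_set`: data.frame with 1-based columns
#'   `left_col`, `right_col`, `center_col`.
#' @export
detect_lanes <- function(img, min_width = NULL) {
  stopifnot(inherits(img, "gel_image"))
  min_width <- min_width %||% max(2L, ceiling(0.01 * img$width))
  prof <- colMeans(img$pixels)
  if (diff(range(prof)) < 1e-6)
    detection_error("no lanes found: image has no column-intensity contrast. Check gel image quality guidelines (even illumination, bands clearly visible).")
  thr <- EBImage::otsu(EBImage::Image(matrix(pmin(pmax(prof, 0), 1), ncol = 1)))
  above <- prof > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_width
  if (!any(keep))
    detection_error("no lanes found above threshold. Check gel image quality guidelines (contrast, lane spacing, straight lanes).")
  lanes <- data.frame(left_col = starts[keep], right_col = ends[keep])
  lanes$center_col <- as.integer(floor((lanes$left_col + lanes$right_col) / 2))
  structure(lanes, class = c("lane_set", "data.frame"))
}

#' Extract per-lane intensity profiles
#'
#' For each lane, the per-row intensity is the mean grey value over a
#' center-aligned band of columns `center +/- band_halfwidth`, clipped to the
#' lane span. Rows run 0..height-1 from the top of the image; lanes are named
#' `lane_1`, `lane_2`, ... left to right.
#'
#' @param img a [gel_image()].
#' @param lanes a `lane_set` from [detect_lanes()].
#' @param band_halfwidth half-width in columns of the central band; default
#'   25% of each lane's span width; 0 uses the single center column.
#' @return a [signal_table()] with `source = "image"`.
#' @export
extract_lane_profiles <- function(img, lanes, band_halfwidth = NULL) {
  stopifnot(inherits(img, "gel_image"), inherits(lanes, "lane_set"))
  if (!is.null(band_halfwidth) && band_halfwidth < 0)
    validation_error("band_halfwidth must be >= 0")
  if (nrow(lanes) == 0L) detection_error("lane set is empty")
  if (any(lanes$left_col < 1L) || any(lanes$right_col > img$width))
    validation_error("lane span outside image bounds")
  prof <- vapply(seq_len(nrow(lanes)), function(k) {
    l <- lanes$left_col[k]; rr <- lanes$right_col[k]; c0 <- lanes$center_col[k]
    hw <- band_halfwidth %||% floor(0.25 * (rr - l + 1L))
    cols <- max(l, c0 - hw):min(rr, c0 + hw)
    rowMeans(img$pixels[, cols, drop = FALSE])
  }, numeric(img$height))
  signal_table(positions = seq_len(img$height) - 1L,
               intensities = prof,
               lane_names = paste0("lane_", seq_len(nrow(lanes))),
               source = "image")
}
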