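# Image input, scale-bar calibration, and the optional preprocessing applied
# before thresholding (crop, mean-filter smoothing, unsharp-mask sharpening).

#' Derive the nm-per-pixel calibration from a scale bar
#'
#' Either pass \code{nmPerPx} directly, or the measured pixel length of the
#' micrograph's scale bar together with its physical length; the calibration
#' is then the exact ratio \code{barLengthNm / barLengthPx} (no rounding).
#'
#' @param nmPerPx direct calibration, nm per pixel.
#' @param barLengthPx scale-bar length in pixels.
#' @param barLengthNm scale-bar physical length in nm.
#' @return nm per pixel as a single positive number.
#' @examples
#' calibrate(barLengthPx = 200, barLengthNm = 100)  # 0.5
#' @export
calibrate <- function(nmPerPx = NULL, barLengthPx = NULL, barLengthNm = NULL) {
  if (!is.null(nmPerPx)) {
    if (length(nmPerPx) != 1 || !is.finite(nmPerPx) || nmPerPx <= 0)
      stop("invalid calibration: nmPerPx must be a single positive number")
    return(as.numeric(nmPerPx))
  }
  if (is.null(barLengthPx) || is.null(barLengthNm))
    stop("invalid calibration: supply nmPerPx or both bar lengths")
  if (barLengthPx <= 0 || barLengthNm <= 0)
    stop("invalid calibration: bar lengths must be positive")
  as.numeric(barLengthNm) / as.numeric(barLengthPx)
}

#' Read a micrograph from a PNG or TIFF file
#'
#' Images are loaded as 8-bit grayscale; RGB(A) input is converted by ITU-R
#' BT.601 luminance (0.299 R + 0.587 G + 0.114 B) before any processing.
#'
#' @param path image file (.png, .tif, .tiff).
#' @param nmPerPx calibration, or use \code{barLengthPx}/\code{barLengthNm}.
#' @param barLengthPx,barLengthNm scale-bar calibration, see [calibrate()].
#' @param label free-text tag stored on the micrograph.
#' @return A [Micrograph-class].
#' @export
readMicrograph <- function(path, nmPerPx = NULL, barLengthPx = NULL,
                           barLengthNm = NULL, label = "") {
  if (!file.exists(path)) stop("cannot read image file: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") png::readPNG(path)
  else if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
  else stop("unsupported image extension: ", ext)
  if (length(dim(img)) == 3) {
    ch <- dim(img)[3]
    img <- if (ch >= 3)
      0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
    else img[, , 1]
  }
  cal <- calibrate(nmPerPx, barLengthPx, barLengthNm)
  Micrograph(round(img * 255), cal, label = label, provenance = path)
}

# separable box mean with replicated borders (exact arithmetic, no FFT)
meanFilter <- function(px, radius) {
  r <- as.integer(radius)
  if (r <= 0) return(px)
  runmean <- function(m) {  # window 2r+1 along the row dimension
    n <- nrow(m) - 2L * r
    cs <- rbind(0, apply(m, 2, cumsum))
    (cs[(2L * r + 2L):(nrow(m) + 1L), , drop = FALSE] -
       cs[seq_len(n), , drop = FALSE]) / (2L * r + 1L)
  }
  pad <- function(n) c(rep(1L, r), seq_len(n), rep(n, r))
  p <- px[pad(nrow(px)), pad(ncol(px)), drop = FALSE]
  out <- runmean(p)
  t(runmean(t(out)))
}

#' Preprocess a micrograph (crop, smooth, sharpen)
#'
#' Operations are applied in the fixed order crop, then smooth, then sharpen.
#' Cropping re-origins the pixel grid but adds the crop offset to the
#' micrograph's nm-space origin, so nm coordinates stay scene-absolute. The
#' calibration is never altered. With no arguments the input is returned
#' gray-identical.
#'
#' @param m a [Micrograph-class].
#' @param crop optional integer \code{c(x, y, width, height)}: 0-based pixel
#'   offset of the crop's top-left corner plus its size; must lie inside the
#'   image.
#' @param smoothRadius optional mean-filter radius in px (kernel side
#'   \code{2r + 1}).
#' @param sharpen logical; unsharp mask \code{m + amount * (m - mean3(m))}.
#' @param sharpenAmount unsharp-mask strength (default 0.6).
#' @return A [Micrograph-class]; gray values clamped to [0, 255] (possibly
#'   fractional after filtering).
#' @export
preprocess <- function(m, crop = NULL, smoothRadius = NULL, sharpen = FALSE,
                       sharpenAmount = 0.6) {
  stopifnot(is(m, "Micrograph"))
  px <- pixels(m)
  off <- offsetNm(m)
  if (!is.null(crop)) {
    stopifnot(length(crop) == 4)
    x <- crop[1]; y <- crop[2]; w <- crop[3]; h <- crop[4]
    if (x < 0 || y < 0 || w < 1 || h < 1 ||
        x + w > ncol(px) || y + h > nrow(px))
      stop(sprintf(
        "crop rectangle (x=%g, y=%g, w=%g, h=%g) outside image bounds %d x %d",
        x, y, w, h, ncol(px), nrow(px)))
    px <- px[(y + 1):(y + h), (x + 1):(x + w), drop = FALSE]
    off <- off + c(x, y) * nmPerPx(m)
  }
  filtered <- FALSE
  if (!is.null(smoothRadius) && smoothRadius > 0) {
    px <- meanFilter(px, smoothRadius)
    filtered <- TRUE
  }
  if (isTRUE(sharpen)) {
    px <- px + sharpenAmount * (px - meanFilter(px, 2L))
    filtered <- TRUE
  }
  if (filtered) px <- pmin(pmax(px, 0), 255)
  Micrograph(px, nmPerPx(m), label = m@label, provenance = m@provenance,
             offsetNm = off)
}

#' Suggest a threshold percentage from the image histogram
#'
#' Computes Otsu's gray-level cutoff and converts it to the threshold
#' percentage used by [thresholdMask()]: the percentage of pixels at or below
#' the cutoff (dark polarity). A convenience for automatic runs; thresholds
#' can always be set manually per image or per window.
#'
#' @param m a [Micrograph-class].
#' @return Threshold percentage in (0, 100].
#' @export
suggestThreshold <- function(m) {
  px <- pixels(m)
  cutoff01 <- EBImage::otsu(EBImage::Image(px / 255), range = c(0, 1))
  100 * mean(px <= cutoff01 * 255)
}
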