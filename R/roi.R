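#' Detect the tissue region of interest by RGB thresholding
#'
#' Estimates the background colour as the per-channel mode of the 1-pixel
#' image border (scan backgrounds are near-uniform white), then marks as
#' tissue every pixel whose Euclidean RGB distance from that colour exceeds
#' `background_distance_threshold`. No morphology is applied here; small
#' speckle is dealt with by [postprocess()].
#'
#' @param pixels HxWx3 raster, 8-bit values.
#' @param background_distance_threshold positive distance in RGB units
#'   (default 30).
#' @return HxW logical mask, `TRUE` for tissue.
#' @export
detect_roi <- function(pixels, background_distance_threshold = 30) {
  d <- dim(pixels)
  if (length(d) != 3 || d[3] != 3) stop("`pixels` must be an HxWx3 array")
  if (background_distance_threshold <= 0) {
    stop("`background_distance_threshold` must be > 0")
  }
  h <- d[1]; w <- d[2]
  if (h == 0 || w == 0) return(matrix(logical(0), h, w))
  border <- c(
    which(row(matrix(0, h, w)) %in% c(1, h)),
    which(col(matrix(0, h, w)) %in% c(1, w))
  )
  border <- unique(border)
  bg <- vapply(1:3, function(ch) {
    v <- as.integer(pixels[, , ch][border])
    tab <- tabulate(v + 1L, nbins = 256L)
    which.max(tab) - 1L  # ties -> smallest value
  }, integer(1))
  d2 <- (pixels[, , 1] - bg[1])^2 + (pixels[, , 2] - bg[2])^2 +
    (pixels[, , 3] - bg[3])^2
  d2 > background_distance_threshold^2
}
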