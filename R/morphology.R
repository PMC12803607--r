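#' Morphological post-processing of a classified label mask
#'
#' Cleans pixelwise classification output the way a histology pipeline
#' removes inappropriate regions: per tissue class (muscle, fibrosis) a
#' morphological opening then closing with a disk structuring element, then
#' removal of connected tissue components (muscle plus fibrosis) smaller
#' than `min_fragment_area_px`, which are relabelled background. Where the
#' per-class cleaned masks overlap, the earlier class in the fixed order
#' (muscle before fibrosis) wins, mirroring the classifier's tie rule.
#'
#' @param labels HxW integer label mask (0/1/2).
#' @param min_fragment_area_px connected tissue components below this pixel
#'   area are dropped (dust, detached micro-fragments).
#' @param opening_radius_px disk radius for opening/closing; 0 skips the
#'   morphological filtering.
#' @return Cleaned HxW integer label mask.
#' @export
postprocess <- function(labels, min_fragment_area_px = 50,
                        opening_radius_px = 1) {
  if (!is.matrix(labels)) stop("`labels` must be a matrix")
  if (opening_radius_px < 0) stop("`opening_radius_px` must be >= 0")
  if (min_fragment_area_px < 0) stop("`min_fragment_area_px` must be >= 0")

  clean <- list()
  for (cls in c("muscle", "fibrosis")) {
    b <- labels == CLASS_CODES[[cls]]
    if (opening_radius_px > 0 && any(b)) {
      brush <- EBImage::makeBrush(2L * as.integer(opening_radius_px) + 1L,
                                  shape = "disc")
      b <- EBImage::closing(EBImage::opening(b * 1L, brush), brush) > 0
    }
    clean[[cls]] <- b
  }
  mus <- clean$muscle
  fib <- clean$fibrosis & !clean$muscle

  out <- matrix(CLASS_CODES[["background"]], nrow(labels), ncol(labels))
  out[mus] <- CLASS_CODES[["muscle"]]
  out[fib] <- CLASS_CODES[["fibrosis"]]

  if (min_fragment_area_px > 0) {
    tissue <- out != CLASS_CODES[["background"]]
    if (any(tissue)) {
      cc <- EBImage::bwlabel(tissue)
      sizes <- tabulate(cc[cc > 0])
      drop <- which(sizes < min_fragment_area_px)
      if (length(drop)) out[cc %in% drop] <- CLASS_CODES[["background"]]
    }
  }
  out
}

#' Convert the default minimum fragment area from mm^2 to pixels
#'
#' @param min_fragment_mm2 area in mm^2 (default 0.01).
#' @param resolution_um_per_px pixel size in micrometres.
#' @return integer pixel count.
#' @export
min_fragment_px <- function(min_fragment_mm2 = 0.01, resolution_um_per_px = 4) {
  as.integer(round(min_fragment_mm2 * 1e6 / resolution_um_per_px^2))
}
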