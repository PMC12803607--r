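#' Write and read a synthetic slide losslessly
#'
#' A slide is stored as three files sharing a prefix: `<prefix>_raster.png`
#' (8-bit RGB), `<prefix>_mask.png` (single-channel PNG with labels
#' 0 = background, 1 = muscle, 2 = fibrosis) and `<prefix>_meta.json`
#' (resolution, fragment id, true CVF). The round trip is bit-exact.
#'
#' @param slide a `synthetic_slide`.
#' @param prefix path prefix (directory must exist).
#' @return `write_slide` returns `prefix` invisibly; `read_slide` returns the
#'   reconstructed `synthetic_slide`.
#' @export
write_slide <- function(slide, prefix) {
  stopifnot(inherits(slide, "synthetic_slide"))
  png::writePNG(slide$pixels / 255, paste0(prefix, "_raster.png"))
  png::writePNG(slide$truth_mask / 255, paste0(prefix, "_mask.png"))
  meta <- list(
    resolution_um_per_px = slide$resolution_um_per_px,
    fragment_id = slide$fragment_id,
    true_cvf_percent = slide$true_cvf_percent
  )
  jsonlite::write_json(meta, paste0(prefix, "_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' @rdname write_slide
#' @export
read_slide <- function(prefix) {
  raster_path <- paste0(prefix, "_raster.png")
  mask_path <- paste0(prefix, "_mask.png")
  meta_path <- paste0(prefix, "_meta.json")
  for (p in c(raster_path, mask_path, meta_path)) {
    if (!file.exists(p)) stop("missing slide component: ", p)
  }
  px <- png::readPNG(raster_path)
  if (length(dim(px)) != 3 || dim(px)[3] < 3) stop("raster is not RGB: ", raster_path)
  pixels <- array(as.integer(round(px[, , 1:3] * 255)), dim = c(dim(px)[1:2], 3))
  mk <- png::readPNG(mask_path)
  if (length(dim(mk)) > 2) stop("mask must be single-channel: ", mask_path)
  mask <- matrix(as.integer(round(mk * 255)), nrow(mk), ncol(mk))
  if (!all(mask %in% CLASS_CODES)) {
    stop("mask contains unknown label values: ",
         paste(setdiff(unique(mask), CLASS_CODES), collapse = ", "))
  }
  if (!all(dim(mask) == dim(pixels)[1:2])) {
    stop("raster and mask dimensions differ")
  }
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (is.null(meta$resolution_um_per_px)) {
    stop("sidecar metadata lacks `resolution_um_per_px`; ",
         "resolution is never defaulted on read")
  }
  structure(
    list(
      pixels = pixels, truth_mask = mask,
      resolution_um_per_px = meta$resolution_um_per_px,
      fragment_id = meta$fragment_id,
      true_cvf_percent = meta$true_cvf_percent
    ),
    class = "synthetic_slide"
  )
}
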