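#' Tissue-class areas of a label mask
#'
#' Counts pixels per class and converts to mm^2 via the pixel size:
#' `mm2 = pixels * resolution_um_per_px^2 / 1e6`.
#'
#' @param labels HxW integer label mask (0/1/2).
#' @param resolution_um_per_px pixel size in micrometres, > 0.
#' @param roi optional logical ROI mask, stored alongside.
#' @param fragment_id optional identifier.
#' @return An object of class `segmentation_result`: list with `areas`
#'   (data.frame class/pixels/mm2), `label_mask`, `roi_mask`,
#'   `resolution_um_per_px`, `fragment_id`.
#' @export
compute_areas <- function(labels, resolution_um_per_px, roi = NULL,
                          fragment_id = NA_character_) {
  if (!is.matrix(labels)) stop("`labels` must be a matrix")
  if (resolution_um_per_px <= 0) stop("`resolution_um_per_px` must be > 0")
  px <- vapply(CLASS_CODES, function(code) sum(labels == code), numeric(1))
  areas <- data.frame(
    class = names(CLASS_CODES),
    pixels = as.numeric(px),
    mm2 = px * resolution_um_per_px^2 / 1e6,
    row.names = NULL
  )
  structure(
    list(areas = areas, label_mask = labels, roi_mask = roi,
         resolution_um_per_px = resolution_um_per_px,
         fragment_id = fragment_id),
    class = "segmentation_result"
  )
}

tissue_mm2 <- function(seg) {
  sum(seg$areas$mm2[seg$areas$class %in% c("muscle", "fibrosis")])
}

class_mm2 <- function(seg, cls) {
  seg$areas$mm2[seg$areas$class == cls]
}

#' Collagen volume fraction from pooled areas
#'
#' `CVF (%) = 100 * total fibrosis area / (total muscle area + total
#' fibrosis area)`. Background is explicitly excluded from the denominator.
#'
#' @param total_fibrosis_mm2,total_muscle_mm2 non-negative areas in mm^2.
#' @return CVF percentage in \[0, 100\].
#' @examples
#' compute_cvf(32, 68) # 32
#' @export
compute_cvf <- function(total_fibrosis_mm2, total_muscle_mm2) {
  if (total_fibrosis_mm2 < 0 || total_muscle_mm2 < 0) {
    stop("areas must be >= 0")
  }
  tot <- total_fibrosis_mm2 + total_muscle_mm2
  if (tot <= 0) stop("no tissue: both areas are zero, CVF undefined")
  100 * total_fibrosis_mm2 / tot
}

#' Per-fragment quality filter
#'
#' Excludes fragments whose tissue area (muscle plus fibrosis) falls below a
#' minimum, recording the reason. Exclusion is per fragment; patient-level
#' usability is decided at aggregation.
#'
#' @param fragments list of `segmentation_result` objects.
#' @param min_tissue_mm2 minimum retained tissue area per fragment.
#' @return list with `retained` (list), `excluded` (list) and `exclusions`
#'   (data.frame fragment_id/tissue_mm2/reason).
#' @export
quality_filter <- function(fragments, min_tissue_mm2 = 0.25) {
  stopifnot(is.list(fragments))
  keep <- logical(length(fragments))
  rows <- list()
  for (i in seq_along(fragments)) {
    tm <- tissue_mm2(fragments[[i]])
    keep[i] <- tm >= min_tissue_mm2
    if (!keep[i]) {
      rows[[length(rows) + 1L]] <- data.frame(
        fragment_id = fragments[[i]]$fragment_id,
        tissue_mm2 = tm,
        reason = sprintf("tissue area %.4f mm2 below minimum %.4f mm2",
                         tm, min_tissue_mm2)
      )
    }
  }
  list(
    retained = fragments[keep],
    excluded = fragments[!keep],
    exclusions = if (length(rows)) do.call(rbind, rows) else
      data.frame(fragment_id = character(), tissue_mm2 = numeric(),
                 reason = character())
  )
}

#' Pool fragments into a per-patient CVF
#'
#' Sums fibrosis and muscle areas over all retained fragments of a patient
#' and applies the CVF formula once on the totals (area-weighted pooling —
#' deliberately not a mean of per-fragment CVFs, which would over-weight
#' small fragments). Using every available fragment minimises sampling bias.
#' Patients whose total retained tissue is below `min_total_tissue_mm2` are
#' flagged as having insufficient tissue for a reliable estimate.
#'
#' @param patient_id identifier.
#' @param fragments non-empty list of retained `segmentation_result`s.
#' @param min_total_tissue_mm2 patient-level minimum total tissue (default
#'   2 mm^2, the standard adequacy criterion for biopsy material).
#' @return An object of class `patient_cvf`: list with `patient_id`,
#'   `total_fibrosis_mm2`, `total_muscle_mm2`, `cvf_percent`, `n_fragments`,
#'   `qc_flag` (`"ok"` or `"insufficient_tissue"`).
#' @export
aggregate_patient <- function(patient_id, fragments,
                              min_total_tissue_mm2 = 2) {
  if (!is.list(fragments) || length(fragments) == 0) {
    stop("patient ", patient_id, ": no retained fragments, CVF undefined")
  }
  fib <- sum(vapply(fragments, class_mm2, numeric(1), cls = "fibrosis"))
  mus <- sum(vapply(fragments, class_mm2, numeric(1), cls = "muscle"))
  structure(
    list(
      patient_id = patient_id,
      n_fragments = length(fragments),
      total_fibrosis_mm2 = fib,
      total_muscle_mm2 = mus,
      cvf_percent = compute_cvf(fib, mus),
      qc_flag = if (fib + mus < min_total_tissue_mm2)
        "insufficient_tissue" else "ok"
    ),
    class = "patient_cvf"
  )
}

#' @export
print.patient_cvf <- function(x, ...) {
  cat(sprintf(
    "<patient_cvf> %s: CVF %.2f%% from %d fragment(s) (%.3f mm2 tissue) [%s]\n",
    x$patient_id, x$cvf_percent, x$n_fragments,
    x$total_fibrosis_mm2 + x$total_muscle_mm2, x$qc_flag
  ))
  invisible(x)
}

#' Run the full quantification pipeline on one slide
#'
#' Convenience wrapper chaining [detect_roi()], [classify_pixels()],
#' [postprocess()] and [compute_areas()] with the package defaults.
#'
#' @param slide a `synthetic_slide` (or any list with `pixels` and
#'   `resolution_um_per_px`).
#' @param clf a trained classifier.
#' @param background_distance_threshold see [detect_roi()].
#' @param opening_radius_px,min_fragment_mm2 see [postprocess()].
#' @return A `segmentation_result`.
#' @export
quantify_slide <- function(slide, clf, background_distance_threshold = 30,
                           opening_radius_px = 1, min_fragment_mm2 = 0.01) {
  roi <- detect_roi(slide$pixels, background_distance_threshold)
  labels <- classify_pixels(slide$pixels, roi, clf)
  labels <- postprocess(
    labels,
    min_fragment_area_px = min_fragment_px(min_fragment_mm2,
                                           slide$resolution_um_per_px),
    opening_radius_px = opening_radius_px
  )
  compute_areas(labels, slide$resolution_um_per_px, roi = roi,
                fragment_id = slide$fragment_id)
}
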