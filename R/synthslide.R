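#' Generate a synthetic stained biopsy fragment with known collagen fraction
#'
#' Builds an RGB raster emulating one endomyocardial biopsy fragment: a
#' connected tissue blob of roughly `area_mm2` on a near-white background,
#' inside which fibrosis is laid down as spatially correlated interstitial
#' patches (a thresholded Gaussian-smoothed noise field) until the planted
#' collagen volume fraction is reached. Pixel colours are drawn from the
#' palette's per-class colour distributions. The ground-truth class mask and
#' the exactly realised CVF are stored alongside the raster, so the
#' quantification pipeline can be validated against a known truth.
#'
#' @param area_mm2 target tissue area in mm^2 (biopsy fragments are typically
#'   1–2 mm^2).
#' @param target_cvf_percent planted collagen volume fraction, in \[0, 100\]:
#'   `100 * fibrosis / (fibrosis + muscle)` by pixel count.
#' @param palette a [stain_palette()].
#' @param blob_scale correlation length (in pixels) of the fibrosis texture;
#'   larger values give coarser patches.
#' @param resolution_um_per_px physical pixel size. The default 4 um/px keeps
#'   a 1–2 mm^2 fragment near 10^5 pixels; scans are commonly acquired at
#'   0.46 um/px and the whole pipeline works identically at that scale.
#' @param fragment_id identifier stored in the slide metadata.
#' @param seed integer seed; the same arguments and seed give a bit-identical
#'   slide.
#' @return An object of class `synthetic_slide`: list with `pixels`
#'   (HxWx3 integer array, 0–255), `truth_mask` (HxW integer matrix,
#'   0 = background, 1 = muscle, 2 = fibrosis), `resolution_um_per_px`,
#'   `fragment_id`, and `true_cvf_percent`.
#' @examples
#' s <- generate_fragment(0.05, 30, stain_palette("trichrome"), seed = 1)
#' s$true_cvf_percent
#' @export
generate_fragment <- function(area_mm2, target_cvf_percent,
                              palette = stain_palette("trichrome"),
                              blob_scale = 6,
                              resolution_um_per_px = 4,
                              fragment_id = "fragment-1",
                              seed = 1L) {
  stopifnot(inherits(palette, "stain_palette"))
  if (!is.numeric(area_mm2) || area_mm2 <= 0) stop("`area_mm2` must be > 0")
  if (blob_scale <= 0) stop("`blob_scale` must be > 0")
  if (resolution_um_per_px <= 0) stop("`resolution_um_per_px` must be > 0")
  if (target_cvf_percent < 0 || target_cvf_percent > 100) {
    stop("`target_cvf_percent` must lie in [0, 100]")
  }
  seed <- check_seed(seed)

  n_tissue <- round(area_mm2 * 1e6 / resolution_um_per_px^2)
  if (n_tissue < 200) {
    stop("target fraction cannot be planted reliably: tissue region of ",
         n_tissue, " px is too small at this resolution; ",
         "increase `area_mm2` or refine `resolution_um_per_px`")
  }
  k_fib <- round(target_cvf_percent / 100 * n_tissue)
  if (k_fib == 0 && target_cvf_percent > 0 ||
      k_fib == n_tissue && target_cvf_percent < 100) {
    stop("target fraction unreachable at this tissue size (rounds to ",
         "an empty class); enlarge `area_mm2`")
  }

  # square canvas with margin so the blob never touches the border
  side <- ceiling(sqrt(n_tissue / 0.55))
  h <- w <- side

  withr::with_seed(seed, {
    # tissue silhouette: long-range smoothed noise plus a radial penalty,
    # thresholded at the exact pixel count -> one dominant central blob
    shape <- smooth_noise(h, w, sigma = side / 8)
    shape <- (shape - mean(shape)) / sd(shape)
    ctr <- (side + 1) / 2
    r2 <- outer((seq_len(h) - ctr)^2, (seq_len(w) - ctr)^2, "+") / (side / 2)^2
    field <- shape - 3 * r2
    thr <- sort(field, decreasing = TRUE)[n_tissue]
    tissue <- field >= thr
    # exact count despite potential threshold ties
    if (sum(tissue) > n_tissue) {
      excess <- which(tissue & field == thr)
      tissue[excess[seq_len(sum(tissue) - n_tissue)]] <- FALSE
    }

    # fibrosis: short-range smoothed noise, top-k pixels within tissue
    tex <- smooth_noise(h, w, sigma = blob_scale)
    tv <- tex[tissue]
    mask <- matrix(CLASS_CODES[["background"]], h, w)
    mask[tissue] <- CLASS_CODES[["muscle"]]
    if (k_fib > 0) {
      ord <- order(tv, decreasing = TRUE)[seq_len(k_fib)]
      idx_tissue <- which(tissue)
      mask[idx_tissue[ord]] <- CLASS_CODES[["fibrosis"]]
    }

    pixels <- array(0L, dim = c(h, w, 3))
    for (cls in names(CLASS_CODES)) {
      idx <- which(mask == CLASS_CODES[[cls]])
      if (length(idx) == 0) next
      cols <- sample_class_colors(length(idx), palette$means[[cls]],
                                  palette$covariances[[cls]])
      for (ch in 1:3) {
        plane <- pixels[, , ch]
        plane[idx] <- cols[, ch]
        pixels[, , ch] <- plane
      }
    }
  })

  true_cvf <- if (n_tissue > 0) 100 * k_fib / n_tissue else NA_real_
  structure(
    list(
      pixels = pixels, truth_mask = mask,
      resolution_um_per_px = resolution_um_per_px,
      fragment_id = fragment_id, true_cvf_percent = true_cvf
    ),
    class = "synthetic_slide"
  )
}

#' @export
print.synthetic_slide <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf(
    "<synthetic_slide> %s: %d x %d px @ %.3g um/px, true CVF %.2f%%\n",
    x$fragment_id, d[1], d[2], x$resolution_um_per_px, x$true_cvf_percent
  ))
  invisible(x)
}

#' Overlay dust and detached micro-fragments on a synthetic slide
#'
#' Adds the small nuisance structures a real scan carries — dark dust specks
#' and detached tissue flecks below the post-processing minimum area — on
#' background regions only. The ground-truth mask keeps labelling them
#' background: they are artefacts, not tissue, and the post-processing stage
#' is expected to remove them.
#'
#' @param slide a `synthetic_slide`.
#' @param n_dust number of dust specks (dark grey, radius 1–2 px).
#' @param n_micro_fragments number of muscle-coloured micro flecks.
#' @param seed integer seed.
#' @return A modified copy of `slide`; `truth_mask` is unchanged.
#' @export
add_artifacts <- function(slide, n_dust = 5, n_micro_fragments = 2, seed = 1L) {
  stopifnot(inherits(slide, "synthetic_slide"))
  if (n_dust < 0 || n_micro_fragments < 0) stop("artifact counts must be >= 0")
  if (n_dust == 0 && n_micro_fragments == 0) return(slide)
  seed <- check_seed(seed)

  h <- dim(slide$pixels)[1]; w <- dim(slide$pixels)[2]
  tissue <- slide$truth_mask != CLASS_CODES[["background"]]
  # keep specks clear of tissue and of each other so each stays its own
  # connected component
  max_r <- 2L
  pal_mu <- c(170, 70, 80)

  withr::with_seed(seed, {
    placed <- matrix(numeric(0), ncol = 2)
    specs <- list()
    total <- n_dust + n_micro_fragments
    tries <- 0L
    while (nrow(placed) < total) {
      tries <- tries + 1L
      if (tries > 20000L) {
        stop("could not place ", total, " artifacts outside tissue; ",
             "image too crowded")
      }
      cy <- sample.int(h - 2 * max_r - 2, 1) + max_r + 1
      cx <- sample.int(w - 2 * max_r - 2, 1) + max_r + 1
      r <- sample(1:max_r, 1)
      win <- tissue[max(1, cy - r - 2):min(h, cy + r + 2),
                    max(1, cx - r - 2):min(w, cx + r + 2)]
      if (any(win)) next
      if (nrow(placed) > 0 &&
          any((placed[, 1] - cy)^2 + (placed[, 2] - cx)^2 <=
              (2 * max_r + 3)^2)) next
      placed <- rbind(placed, c(cy, cx))
      specs[[length(specs) + 1L]] <- c(cy, cx, r)
    }
    px <- slide$pixels
    for (i in seq_along(specs)) {
      s <- specs[[i]]
      is_dust <- i <= n_dust
      dy <- seq(s[1] - s[3], s[1] + s[3])
      dx <- seq(s[2] - s[3], s[2] + s[3])
      for (y in dy) for (x in dx) {
        if ((y - s[1])^2 + (x - s[2])^2 > s[3]^2) next
        base <- if (is_dust) c(55, 55, 55) else pal_mu
        col <- pmin(pmax(round(base + rnorm(3, 0, 8)), 0), 255)
        px[y, x, ] <- as.integer(col)
      }
    }
    slide$pixels <- px
  })
  slide
}

#' Sample labelled training pixels from a slide's ground truth
#'
#' Emulates the manual annotation step that trains the pixel classifier:
#' draws `n_per_class` colour samples per class, uniformly without
#' replacement, from the truth-labelled pixels of a slide.
#'
#' @param slide a `synthetic_slide`.
#' @param n_per_class samples per class.
#' @param seed integer seed.
#' @return A [pixel_training_set()] with `3 * n_per_class` rows.
#' @export
sample_training_pixels <- function(slide, n_per_class = 200, seed = 1L) {
  stopifnot(inherits(slide, "synthetic_slide"))
  seed <- check_seed(seed)
  out <- withr::with_seed(seed, {
    rows <- lapply(names(CLASS_CODES), function(cls) {
      idx <- which(slide$truth_mask == CLASS_CODES[[cls]])
      if (length(idx) < n_per_class) {
        stop("class '", cls, "' has only ", length(idx),
             " pixels; cannot sample ", n_per_class)
      }
      pick <- sample(idx, n_per_class)
      h <- dim(slide$pixels)[1]
      data.frame(
        r = slide$pixels[, , 1][pick],
        g = slide$pixels[, , 2][pick],
        b = slide$pixels[, , 3][pick],
        label = cls
      )
    })
    do.call(rbind, rows)
  })
  pixel_training_set(out, provenance = slide$fragment_id)
}
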