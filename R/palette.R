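#' Stain colour palette for synthetic slides
#'
#' Describes the per-class RGB colour distribution of a histology stain:
#' a mean colour and a positive-definite 3x3 colour covariance for each of
#' the three tissue classes (muscle, fibrosis, background). Both Masson's
#' trichrome and AFOG render collagen blue and muscle red/orange against a
#' near-white background; the default numbers are package conventions chosen
#' to look like typical scans, not measurements of any particular scanner.
#'
#' @param stain_name `"trichrome"` or `"afog"`.
#' @param means named list of 3-vectors (`muscle`, `fibrosis`, `background`)
#'   in \[0, 255\]; defaults depend on `stain_name`.
#' @param covariances named list of 3x3 positive-definite matrices; default is
#'   diagonal with standard deviation 12 per channel for tissue and 4 for
#'   background.
#' @return An object of class `stain_palette`.
#' @examples
#' pal <- stain_palette("trichrome")
#' pal$means$fibrosis
#' @export
stain_palette <- function(stain_name = c("trichrome", "afog"),
                          means = NULL, covariances = NULL) {
  stain_name <- match.arg(stain_name)
  default_means <- switch(stain_name,
    trichrome = list(
      muscle = c(180, 60, 70),
      fibrosis = c(70, 90, 170),
      background = c(245, 245, 245)
    ),
    afog = list(
      muscle = c(210, 110, 50),
      fibrosis = c(60, 80, 180),
      background = c(245, 245, 245)
    )
  )
  if (is.null(means)) means <- default_means
  if (is.null(covariances)) {
    covariances <- list(
      muscle = diag(12^2, 3), fibrosis = diag(12^2, 3),
      background = diag(4^2, 3)
    )
  }
  cls <- c("muscle", "fibrosis", "background")
  stopifnot(all(cls %in% names(means)), all(cls %in% names(covariances)))
  for (k in cls) {
    m <- means[[k]]
    if (length(m) != 3 || any(m < 0) || any(m > 255)) {
      stop("mean colour for class '", k, "' must be a 3-vector in [0, 255]")
    }
    if (!is_pos_def(covariances[[k]])) {
      stop("colour covariance for class '", k,
           "' must be symmetric positive-definite")
    }
  }
  d <- utils::combn(cls, 2, function(p) {
    sqrt(sum((means[[p[1]]] - means[[p[2]]])^2))
  })
  if (any(d == 0)) stop("class mean colours must be pairwise distinct")
  structure(
    list(stain_name = stain_name, means = means, covariances = covariances),
    class = "stain_palette"
  )
}

#' @export
print.stain_palette <- function(x, ...) {
  cat("<stain_palette>", x$stain_name, "\n")
  for (k in names(x$means)) {
    cat(sprintf("  %-10s mean RGB (%s)\n", k,
                paste(round(x$means[[k]]), collapse = ", ")))
  }
  invisible(x)
}
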