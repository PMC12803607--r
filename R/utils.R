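#' Round half-up to a fixed number of decimals
#'
#' Base [round()] uses round-half-to-even; printed clinical percentages follow
#' the half-up convention (e.g. 2.105 -> 2.11), so reporting helpers use this.
#'
#' @param x numeric vector.
#' @param digits non-negative integer number of decimal places.
#' @return numeric vector rounded half-up.
#' @examples
#' round_half_up(0.765, 2) # 0.77
#' @export
round_half_up <- function(x, digits = 0) {
  stopifnot(is.numeric(x), digits >= 0)
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

# single checkpoint for "must be a scalar seed" validation
check_seed <- function(seed) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing integer", call. = FALSE)
  }
  as.integer(seed)
}

# smooth a white-noise field; EBImage's Gaussian blur does the heavy lifting
smooth_noise <- function(h, w, sigma) {
  z <- matrix(rnorm(h * w), h, w)
  if (sigma > 0) {
    # gblur needs the filter to fit inside the image
    sigma <- min(sigma, floor((min(h, w) - 1) / 8))
    if (sigma > 0) z <- EBImage::gblur(z, sigma = sigma)
  }
  z
}

# draw n RGB colours from N(mean, cov), clipped to [0, 255] and quantised
sample_class_colors <- function(n, mean_color, cov) {
  z <- matrix(rnorm(n * 3), n, 3) %*% chol(cov)
  z <- sweep(z, 2, mean_color, "+")
  matrix(as.integer(pmin(pmax(round(z), 0), 255)), n, 3)
}

is_pos_def <- function(m, tol = 1e-10) {
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-8))) return(FALSE)
  all(eigen(m, symmetric = TRUE, only.values = TRUE)$values > tol * sum(diag(m)))
}
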