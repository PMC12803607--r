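#' Labelled pixel colour samples for classifier training
#'
#' @param samples data.frame with integer columns `r`, `g`, `b` in
#'   \[0, 255\] and a `label` column with values among
#'   `"background"`, `"muscle"`, `"fibrosis"`.
#' @param provenance character vector of fragment ids the samples came from.
#' @return An object of class `pixel_training_set`.
#' @export
pixel_training_set <- function(samples, provenance = character()) {
  stopifnot(is.data.frame(samples),
            all(c("r", "g", "b", "label") %in% names(samples)))
  if (!all(samples$label %in% CLASS_LEVELS)) {
    stop("labels must be among: ", paste(CLASS_LEVELS, collapse = ", "))
  }
  tab <- table(samples$label)
  if (length(tab) < 2) stop("training set must contain at least 2 classes")
  if (any(tab < 10)) {
    stop("each present class needs >= 10 samples; short: ",
         paste(names(tab)[tab < 10], collapse = ", "))
  }
  structure(list(samples = samples, provenance = provenance),
            class = "pixel_training_set")
}

#' Train the linear Bayesian pixel classifier
#'
#' Fits Gaussian class-conditional densities in RGB colour space with a
#' shared (pooled within-class) covariance — the canonical linear Bayes
#' rule, equivalent to linear discriminant analysis. Class means are the
#' per-class sample means; the pooled covariance is ridge-regularised with
#' `1e-3 * trace(S)/3 * I` if near-singular.
#'
#' @param training a [pixel_training_set()].
#' @param prior_mode `"equal"` (default: annotated region sizes are
#'   annotator-dependent, so equal priors are the neutral choice) or
#'   `"empirical"` (training class frequencies).
#' @return An object of class `linear_bayes_classifier` with fields
#'   `class_means`, `shared_covariance`, `priors`, `classes`.
#' @export
train_classifier <- function(training, prior_mode = c("equal", "empirical")) {
  stopifnot(inherits(training, "pixel_training_set"))
  prior_mode <- match.arg(prior_mode)
  s <- training$samples
  classes <- CLASS_LEVELS[CLASS_LEVELS %in% unique(s$label)]
  X <- as.matrix(s[, c("r", "g", "b")])
  n <- nrow(X)
  means <- lapply(setNames(classes, classes), function(k) {
    colMeans(X[s$label == k, , drop = FALSE])
  })
  pooled <- matrix(0, 3, 3)
  for (k in classes) {
    Xi <- X[s$label == k, , drop = FALSE]
    d <- sweep(Xi, 2, means[[k]])
    pooled <- pooled + crossprod(d)
  }
  pooled <- pooled / (n - length(classes))
  ev <- eigen(pooled, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-8 * sum(diag(pooled)) || sum(diag(pooled)) == 0) {
    pooled <- pooled + diag(1e-3 * max(sum(diag(pooled)) / 3, 1), 3)
  }
  if (min(eigen(pooled, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
    stop("pooled colour covariance is singular even after regularisation")
  }
  priors <- switch(prior_mode,
    equal = rep(1 / length(classes), length(classes)),
    empirical = as.numeric(table(factor(s$label, classes)) / n)
  )
  names(priors) <- classes
  structure(
    list(class_means = means, shared_covariance = pooled,
         priors = priors, classes = classes, prior_mode = prior_mode),
    class = "linear_bayes_classifier"
  )
}

#' @export
print.linear_bayes_classifier <- function(x, ...) {
  cat("<linear_bayes_classifier>", length(x$classes), "classes;",
      x$prior_mode, "priors\n")
  for (k in x$classes) {
    cat(sprintf("  %-10s mean RGB (%s)\n", k,
                paste(round(x$class_means[[k]], 1), collapse = ", ")))
  }
  invisible(x)
}

#' Classify every ROI pixel of a raster
#'
#' Assigns each pixel inside the region of interest to the class maximising
#' the linear discriminant
#' `delta_k(x) = x' S^-1 mu_k - mu_k' S^-1 mu_k / 2 + log pi_k`.
#' Ties — scores equal up to a small numerical tolerance — are broken by
#' the fixed class order background < muscle < fibrosis; pixels outside
#' the ROI are labelled background.
#'
#' @param pixels HxWx3 raster, 8-bit values.
#' @param roi HxW logical ROI mask (see [detect_roi()]).
#' @param clf a trained [train_classifier()] model with the three canonical
#'   classes.
#' @return HxW integer label mask (0 = background, 1 = muscle, 2 = fibrosis).
#' @export
classify_pixels <- function(pixels, roi, clf) {
  stopifnot(inherits(clf, "linear_bayes_classifier"))
  d <- dim(pixels)
  if (length(d) != 3 || d[3] != 3) stop("`pixels` must be an HxWx3 array")
  if (!all(dim(roi) == d[1:2])) stop("raster and ROI dimensions differ")
  if (!identical(clf$classes, CLASS_LEVELS)) {
    stop("classifier must be trained on all three canonical classes")
  }
  labels <- matrix(CLASS_CODES[["background"]], d[1], d[2])
  idx <- which(roi)
  if (length(idx) == 0) return(labels)
  X <- cbind(pixels[, , 1][idx], pixels[, , 2][idx], pixels[, , 3][idx])
  labels[idx] <- discriminant_argmax(X, clf)
  labels
}

# delta_k for an n x 3 colour matrix; returns class codes of the argmax.
# Ties are resolved to the first class in the fixed order; scores within a
# tiny relative tolerance of the maximum count as tied, so algebraically
# exact ties (e.g. a pixel at the midpoint of two means under isotropic
# covariance) are not broken by floating-point rounding.
discriminant_argmax <- function(X, clf) {
  Sinv <- solve(clf$shared_covariance)
  M <- do.call(cbind, clf$class_means[clf$classes])  # 3 x K
  A <- Sinv %*% M
  const <- -0.5 * colSums(M * A) + log(clf$priors[clf$classes])
  scores <- X %*% A + rep(const, each = nrow(X))
  m <- do.call(pmax, as.data.frame(scores))
  tol <- 1e-9 * (1 + abs(m))
  CLASS_CODES[clf$classes][max.col(scores >= m - tol, ties.method = "first")]
}
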