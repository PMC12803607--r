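#' Restricted cubic spline basis
#'
#' Builds the restricted (natural) cubic spline basis in Harrell's
#' truncated-power parameterisation: with knots `t_1 < ... < t_k` the basis
#' is `x` plus `k - 2` nonlinear columns
#' \deqn{B_j(x) = [(x - t_j)_+^3 - (x - t_{k-1})_+^3 (t_k - t_j)/(t_k -
#' t_{k-1}) + (x - t_k)_+^3 (t_{k-1} - t_j)/(t_k - t_{k-1})] / (t_k - t_1)^2}
#' which is linear beyond the boundary knots by construction.
#'
#' @param x numeric vector.
#' @param n_knots number of knots when `knots` is not given; placed at the
#'   quantiles 0.05/0.35/0.65/0.95 for the default 4.
#' @param knots optional explicit knot locations (>= 3 distinct values).
#' @return An object of class `spline_basis`: list with `knots` and
#'   `basis` (matrix, first column `x`, then the nonlinear terms).
#' @export
rcs_basis <- function(x, n_knots = 4, knots = NULL) {
  if (is.null(knots)) {
    probs <- switch(as.character(n_knots),
      "3" = c(0.10, 0.50, 0.90),
      "4" = c(0.05, 0.35, 0.65, 0.95),
      "5" = c(0.05, 0.275, 0.50, 0.725, 0.95),
      seq(0.05, 0.95, length.out = n_knots)
    )
    knots <- unname(quantile(x, probs, na.rm = TRUE, type = 7))
  }
  knots <- sort(unique(knots))
  k <- length(knots)
  if (k < 3) stop("need at least 3 distinct knots; got ", k)
  tk <- knots[k]; tk1 <- knots[k - 1]; t1 <- knots[1]
  pos3 <- function(u) pmax(u, 0)^3
  nl <- vapply(seq_len(k - 2), function(j) {
    tj <- knots[j]
    (pos3(x - tj) -
       pos3(x - tk1) * (tk - tj) / (tk - tk1) +
       pos3(x - tk) * (tk1 - tj) / (tk - tk1)) / (tk - t1)^2
  }, numeric(length(x)))
  basis <- cbind(x, matrix(nl, nrow = length(x)))
  colnames(basis) <- c("x", paste0("x_rcs", seq_len(k - 2)))
  structure(list(knots = knots, basis = basis), class = "spline_basis")
}

#' Likelihood-ratio test for nonlinearity of a covariate effect
#'
#' Compares, by likelihood ratio, the Cox model using the full restricted
#' cubic spline expansion of `term` against the model with `term` linear.
#' A small p-value means the spline's extra curvature significantly
#' improves fit, i.e. the log-hazard is nonlinear in the covariate.
#'
#' @param data data.frame.
#' @param term name of a numeric column.
#' @param n_knots knots for the spline (default 4, i.e. 2 nonlinear df).
#' @param time_col,event_col survival columns as in [fit_cox()].
#' @return list with `p_value`, `chi_square`, `df`, `logpl_linear`,
#'   `logpl_spline`, `knots`.
#' @export
nonlinearity_test <- function(data, term, n_knots = 4,
                              time_col = "time_composite_years",
                              event_col = "event_composite") {
  x <- data[[term]]
  if (is.null(x) || !is.numeric(x)) stop("`term` must name a numeric column")
  cc <- complete.cases(x, data[[time_col]], data[[event_col]])
  d <- data[cc, , drop = FALSE]
  sb <- rcs_basis(d[[term]], n_knots = n_knots)
  if (length(unique(d[[term]])) <= n_knots) {
    stop("too few distinct values in `", term, "` for ", n_knots, " knots")
  }
  work <- d[, c(time_col, event_col), drop = FALSE]
  work$x_lin <- sb$basis[, 1]
  nl_cols <- colnames(sb$basis)[-1]
  for (cn in nl_cols) work[[cn]] <- sb$basis[, cn]
  lin <- fit_cox(work, "x_lin", time_col = time_col, event_col = event_col)
  spl <- fit_cox(work, c("x_lin", nl_cols),
                 time_col = time_col, event_col = event_col)
  lr <- 2 * (spl$log_partial_likelihood - lin$log_partial_likelihood)
  df <- length(nl_cols)
  list(
    p_value = pchisq(max(lr, 0), df = df, lower.tail = FALSE),
    chi_square = max(lr, 0), df = df,
    logpl_linear = lin$log_partial_likelihood,
    logpl_spline = spl$log_partial_likelihood,
    knots = sb$knots
  )
}
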