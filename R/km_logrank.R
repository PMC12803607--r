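#' Kaplan-Meier product-limit estimate
#'
#' @param times non-negative follow-up times.
#' @param events 0/1 event indicators (0 = censored).
#' @param group_label optional label stored with the curve.
#' @return An object of class `km_curve`: data.frame-backed list with
#'   `time` (distinct event times, ascending), `n_risk`, `n_event`,
#'   `survival` (step-function values), plus `n` and `group_label`.
#'   `S(0) = 1`; the survival values are non-increasing.
#' @examples
#' km <- km_estimate(c(5, 10, 15), c(0, 1, 1))
#' km$survival # 0.5 after t=10, 0 after t=15
#' @export
km_estimate <- function(times, events, group_label = NA_character_) {
  check_surv_input(times, events)
  o <- order(times)
  t_s <- times[o]; e_s <- events[o]
  ut <- unique(t_s[e_s == 1])
  n <- length(t_s)
  if (length(ut) == 0) {
    return(structure(list(time = numeric(0), n_risk = numeric(0),
                          n_event = numeric(0), survival = numeric(0),
                          n = n, group_label = group_label),
                     class = "km_curve"))
  }
  first_pos <- match(ut, t_s)
  n_risk <- n - first_pos + 1
  n_event <- vapply(ut, function(u) sum(e_s[t_s == u]), numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  structure(
    list(time = ut, n_risk = n_risk, n_event = n_event, survival = surv,
         n = n, group_label = group_label),
    class = "km_curve"
  )
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#'
#' @param km a `km_curve`.
#' @param at times at which to read the step function.
#' @return survival probabilities.
#' @export
km_survival_at <- function(km, at) {
  stopifnot(inherits(km, "km_curve"))
  vapply(at, function(t) {
    i <- findInterval(t, km$time)
    if (i == 0) 1 else km$survival[i]
  }, numeric(1))
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> n=%d%s, %d event time(s)\n", x$n,
              if (is.na(x$group_label)) "" else
                paste0(" [", x$group_label, "]"),
              length(x$time)))
  invisible(x)
}

#' Two-group log-rank (Mantel-Haenszel) test
#'
#' Tallies observed and expected events over the risk set at every distinct
#' event time: `U = sum(O1j - E1j)` with `E1j = n1j * dj / nj`, variance
#' `V = sum(n1j n2j dj (nj - dj) / (nj^2 (nj - 1)))`, and
#' `chi^2 = U^2 / V` on 1 degree of freedom.
#'
#' @param times,events follow-up times and 0/1 event indicators.
#' @param group logical or two-level vector splitting subjects into two
#'   non-empty groups.
#' @return An object of class `logrank_result`: list with `chi_square`,
#'   `df`, `p_value`, and per-group `observed` / `expected` event counts.
#' @export
logrank_test <- function(times, events, group) {
  check_surv_input(times, events)
  if (length(group) != length(times)) stop("`group` length mismatch")
  g <- as.factor(group)
  if (nlevels(g) != 2) stop("`group` must define exactly two groups")
  if (any(table(g) == 0)) stop("both groups must be non-empty")
  g1 <- g == levels(g)[2]

  o <- order(times)
  t_s <- times[o]; e_s <- events[o]; g_s <- g1[o]
  n <- length(t_s)
  ut <- unique(t_s[e_s == 1])
  suffix_g1 <- rev(cumsum(rev(g_s)))
  first_pos <- match(ut, t_s)
  n_j <- n - first_pos + 1
  n1_j <- suffix_g1[first_pos]
  d_j <- vapply(ut, function(u) sum(e_s[t_s == u]), numeric(1))
  d1_j <- vapply(ut, function(u) sum(e_s[t_s == u & g_s]), numeric(1))

  e1_j <- n1_j * d_j / n_j
  v_j <- ifelse(n_j > 1,
                d_j * (n1_j / n_j) * (1 - n1_j / n_j) * (n_j - d_j) / (n_j - 1),
                0)
  U <- sum(d1_j - e1_j)
  V <- sum(v_j)
  chi <- if (V > 0) U^2 / V else 0
  p <- if (V > 0) pchisq(chi, df = 1, lower.tail = FALSE) else 1
  obs <- c(sum(d_j) - sum(d1_j), sum(d1_j))
  expd <- c(sum(d_j) - sum(e1_j), sum(e1_j))
  names(obs) <- names(expd) <- levels(g)
  structure(
    list(chi_square = chi, df = 1L, p_value = p,
         observed = obs, expected = expd),
    class = "logrank_result"
  )
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("<logrank_result> chi-square = %.4g on %d df, p = %.4g\n",
              x$chi_square, x$df, x$p_value))
  invisible(x)
}

check_surv_input <- function(times, events) {
  if (length(times) == 0) stop("empty survival input")
  if (length(times) != length(events)) stop("times/events length mismatch")
  if (any(is.na(times)) || any(is.na(events))) {
    stop("times and events must not contain NA")
  }
  if (any(times < 0)) stop("times must be >= 0")
  if (!all(events %in% c(0, 1))) stop("events must be 0/1")
  invisible(TRUE)
}
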