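#' Percentage with half-up rounding
#'
#' `100 * count / n`, rounded half-up to `decimals` places — the convention
#' used for printed complication and event rates.
#'
#' @param count,n non-negative integers with `count <= n`, `n > 0`.
#' @param decimals decimal places.
#' @return percentage.
#' @examples
#' proportion_percent(4, 524, 2) # 0.76
#' @export
proportion_percent <- function(count, n, decimals = 1) {
  if (n <= 0) stop("`n` must be > 0")
  if (count < 0 || count > n) stop("need 0 <= count <= n")
  round_half_up(100 * count / n, decimals)
}

#' Per-group event-rate table
#'
#' Formats event counts per group as percentages at one decimal, optionally
#' with the group-comparison log-rank p alongside.
#'
#' @param event_counts named integer vector of events per group.
#' @param group_sizes integer vector of group sizes (same order/names).
#' @param p_value optional log-rank p for the group comparison.
#' @return data.frame with `group`, `events`, `n`, `rate_percent` and, if
#'   given, `p_value` on the first row.
#' @examples
#' event_rate_table(c(high = 48, low = 14), c(high = 264, low = 260))
#' @export
event_rate_table <- function(event_counts, group_sizes, p_value = NULL) {
  if (length(event_counts) != length(group_sizes)) {
    stop("counts and sizes must align")
  }
  if (any(group_sizes <= 0)) stop("group sizes must be > 0")
  if (any(event_counts > group_sizes)) stop("counts cannot exceed sizes")
  out <- data.frame(
    group = if (is.null(names(event_counts)))
      paste0("group", seq_along(event_counts)) else names(event_counts),
    events = as.numeric(event_counts),
    n = as.numeric(group_sizes),
    rate_percent = vapply(seq_along(event_counts), function(i) {
      proportion_percent(event_counts[i], group_sizes[i], 1)
    }, numeric(1)),
    row.names = NULL
  )
  if (!is.null(p_value)) {
    out$p_value <- c(p_value, rep(NA_real_, nrow(out) - 1))
  }
  out
}

#' Compare a variable between two groups with the matching test
#'
#' Dispatches on the declared variable type — never inferred from the data:
#' `"mean"` uses Welch's t-test and reports mean (SD); `"median"` uses the
#' Mann-Whitney U test and reports median \[IQR\]; `"categorical"` uses the
#' chi-squared test and reports n (%).
#'
#' @param data data.frame.
#' @param group name of a two-level grouping column.
#' @param variable name of the column to compare.
#' @param type one of `"mean"`, `"median"`, `"categorical"`.
#' @return list with `p_value`, `test`, and `descriptives` (one row per
#'   group; for categorical, one row per group x level).
#' @export
compare_groups <- function(data, group, variable,
                           type = c("mean", "median", "categorical")) {
  type <- match.arg(type)
  g <- as.factor(data[[group]])
  if (nlevels(g) != 2) stop("`group` must have exactly two levels")
  if (any(table(g) == 0)) stop("both groups must be non-empty")
  x <- data[[variable]]
  keep <- !is.na(x) & !is.na(g)
  x <- x[keep]; g <- droplevels(g[keep])
  split_x <- split(x, g)
  if (type == "mean") {
    ht <- t.test(x ~ g)
    desc <- data.frame(
      group = names(split_x),
      summary = vapply(split_x, function(v) {
        sprintf("%.1f (%.1f)", mean(v), sd(v))
      }, character(1)),
      row.names = NULL
    )
    list(p_value = ht$p.value, test = "t-test", descriptives = desc)
  } else if (type == "median") {
    ht <- suppressWarnings(wilcox.test(x ~ g))
    desc <- data.frame(
      group = names(split_x),
      summary = vapply(split_x, function(v) {
        q <- quantile(v, c(0.25, 0.5, 0.75))
        sprintf("%.1f [%.1f; %.1f]", q[2], q[1], q[3])
      }, character(1)),
      row.names = NULL
    )
    list(p_value = ht$p.value, test = "mann-whitney", descriptives = desc)
  } else {
    tab <- table(g, x)
    p <- if (nrow(unique(matrix(prop.table(tab, 1), nrow = 2))) == 1) {
      1  # identical proportions: no evidence of difference by definition
    } else {
      suppressWarnings(chisq.test(tab))$p.value
    }
    desc <- as.data.frame(tab)
    names(desc) <- c("group", "level", "n")
    desc$percent <- vapply(seq_len(nrow(desc)), function(i) {
      proportion_percent(desc$n[i], sum(tab[desc$group[i], ]), 1)
    }, numeric(1))
    list(p_value = p, test = "chi-squared", descriptives = desc)
  }
}

#' Correlation of a percentage (on the logit scale) with another variable
#'
#' Pearson correlation of `logit(x/100)` with `y`, with a Fisher-z 95%
#' confidence interval. Percentages exactly at 0 or 100 have no logit;
#' supply `clamp_epsilon` to clamp into `[eps, 100 - eps]`, otherwise such
#' values are an error.
#'
#' @param x_percent percentages in (0, 100).
#' @param y numeric vector of equal length.
#' @param clamp_epsilon optional clamp in percentage points (default 0: no
#'   clamping).
#' @return list with `r`, `ci95` (length 2), `p_value`, `n`.
#' @export
logit_correlation <- function(x_percent, y, clamp_epsilon = 0) {
  stopifnot(length(x_percent) == length(y))
  keep <- complete.cases(x_percent, y)
  x <- x_percent[keep]; yy <- y[keep]
  if (clamp_epsilon > 0) {
    x <- pmin(pmax(x, clamp_epsilon), 100 - clamp_epsilon)
  }
  if (any(x <= 0 | x >= 100)) {
    stop("percentages at or beyond 0/100 have no logit; ",
         "set `clamp_epsilon` > 0 to clamp")
  }
  lx <- qlogis(x / 100)
  if (sd(lx) == 0 || sd(yy) == 0) stop("zero variance in an input vector")
  ct <- cor.test(lx, yy, method = "pearson")
  list(r = unname(ct$estimate), ci95 = as.numeric(ct$conf.int),
       p_value = ct$p.value, n = length(lx))
}
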