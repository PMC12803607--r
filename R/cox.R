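#' Fit a Cox proportional-hazards model
#'
#' Thin, typed wrapper around [survival::coxph()] that returns the pieces
#' the reporting layer needs: per-term hazard ratios with 95% CIs
#' (`exp(coef +- 1.96 se)`), Wald p-values, the maximised log partial
#' likelihood and `AIC = -2 logPL + 2k`. Efron's tie handling is the
#' default. Monotone-likelihood fits (perfect separation) are flagged.
#'
#' @param data data.frame containing the model columns.
#' @param terms character vector of right-hand-side terms.
#' @param time_col,event_col names of the follow-up time and 0/1 event
#'   columns (defaults target the composite endpoint of the cohort tables).
#' @param ties `"efron"` or `"breslow"`.
#' @return An object of class `cox_model`: list with `terms` (data.frame
#'   term/coef/se/hr/ci_lo/ci_hi/p), `log_partial_likelihood`, `n`,
#'   `n_events`, `k`, `aic`, `flags`.
#' @export
fit_cox <- function(data, terms,
                    time_col = "time_composite_years",
                    event_col = "event_composite",
                    ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  stopifnot(is.data.frame(data), length(terms) >= 1)
  if (!all(c(time_col, event_col) %in% names(data))) {
    stop("missing time/event columns: ", time_col, ", ", event_col)
  }
  if (sum(data[[event_col]], na.rm = TRUE) < 1) {
    stop("at least one event is required")
  }
  f <- as.formula(paste0(
    "survival::Surv(", time_col, ", ", event_col, ") ~ ",
    paste(terms, collapse = " + ")
  ))
  flags <- character()
  fit <- withCallingHandlers(
    survival::coxph(f, data = data, ties = ties,
                    control = survival::coxph.control(eps = 1e-10)),
    warning = function(w) {
      # convergence problems (monotone likelihood, separation) become flags
      flags <<- c(flags, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  co <- fit$coefficients
  se <- sqrt(diag(fit$var))
  if (any(!is.finite(co)) || any(abs(co) > 15) || any(se > 1e3)) {
    flags <- c(flags, "possible monotone likelihood (separation)")
  }
  if (!is.null(fit$info) && isTRUE(fit$info$convergence != 0)) {
    flags <- c(flags, "non-convergence reported")
  }
  logpl <- fit$loglik[length(fit$loglik)]
  k <- length(co)
  tab <- data.frame(
    term = names(co), coef = unname(co), se = unname(se),
    hr = exp(unname(co)),
    ci_lo = exp(unname(co) - 1.96 * unname(se)),
    ci_hi = exp(unname(co) + 1.96 * unname(se)),
    p = 2 * pnorm(-abs(unname(co) / unname(se))),
    row.names = NULL
  )
  structure(
    list(terms = tab, log_partial_likelihood = logpl,
         n = fit$n, n_events = fit$nevent, k = k,
         aic = -2 * logpl + 2 * k, ties = ties, flags = flags,
         fit = fit),
    class = "cox_model"
  )
}

#' @export
print.cox_model <- function(x, digits = 3, ...) {
  cat(sprintf("<cox_model> n=%d, events=%d, logPL=%.3f, AIC=%.1f\n",
              x$n, x$n_events, x$log_partial_likelihood, x$aic))
  tab <- x$terms
  tab$hr_ci <- sprintf("%.2f (%.2f-%.2f)", tab$hr, tab$ci_lo, tab$ci_hi)
  print(tab[, c("term", "hr_ci", "p")], digits = digits, row.names = FALSE)
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

# fit a Cox model on each imputed dataset, pool by Rubin's rules, average
# AIC; a single (complete-data) dataset needs no pooling
fit_cox_mi <- function(datasets, terms, time_col, event_col,
                       ties = "efron") {
  fits <- lapply(datasets, function(d) {
    fit_cox(d, terms, time_col = time_col, event_col = event_col, ties = ties)
  })
  pooled <- if (length(fits) == 1) fits[[1]]$terms else
    pool_rubin(lapply(fits, function(f) f$terms))
  list(
    pooled = pooled,
    aic = mean(vapply(fits, function(f) f$aic, numeric(1))),
    fits = fits
  )
}

#' Single-predictor and CVF-adjusted Cox model ladder
#'
#' For each candidate predictor, fits the single-predictor Cox model and the
#' two-predictor model additionally adjusted for the fibrosis term, on a
#' stack of (multiply imputed) datasets with Rubin pooling; model AICs are
#' averaged across imputations. A lower adjusted AIC than every
#' single-predictor AIC is the signature of the fibrosis term carrying
#' independent prognostic information. Predictors collinear with the
#' adjustment term are flagged rather than silently dropped; per-row fit
#' failures are recorded and do not abort the table.
#'
#' @param datasets a list of imputed data.frames (an
#'   [impute_pmm_bootstrap()] result's `datasets`), or a single complete
#'   data.frame.
#' @param predictors character vector of predictor terms.
#' @param adjust_for the adjustment term (default `"cvf_percent"`).
#' @param time_col,event_col survival columns, as in [fit_cox()].
#' @return data.frame with one row per predictor: pooled hazard ratio, CI
#'   and p for the predictor in each model, both AICs, and a `note` column.
#' @export
two_predictor_ladder <- function(datasets, predictors,
                                 adjust_for = "cvf_percent",
                                 time_col = "time_composite_years",
                                 event_col = "event_composite") {
  if (is.data.frame(datasets)) datasets <- list(datasets)
  if (length(predictors) == 0) {
    return(data.frame(
      predictor = character(), hr_single = numeric(), p_single = numeric(),
      aic_single = numeric(), hr_adjusted = numeric(), p_adjusted = numeric(),
      aic_adjusted = numeric(), note = character()
    ))
  }
  rows <- lapply(predictors, function(pr) {
    note <- ""
    x <- datasets[[1]][[pr]]
    adj <- datasets[[1]][[adjust_for]]
    if (!is.null(x) && !is.null(adj) && is.numeric(x) && is.numeric(adj)) {
      cc <- complete.cases(x, adj)
      if (sum(cc) > 2 && sd(x[cc]) > 0 && sd(adj[cc]) > 0 &&
          abs(cor(x[cc], adj[cc])) > 0.999) {
        note <- paste0("collinear with ", adjust_for)
      }
    }
    single <- tryCatch(
      fit_cox_mi(datasets, pr, time_col, event_col),
      error = function(e) e
    )
    adjusted <- tryCatch(
      fit_cox_mi(datasets, c(pr, adjust_for), time_col, event_col),
      error = function(e) e
    )
    pick <- function(fit, which_term) {
      if (inherits(fit, "error")) {
        return(c(hr = NA_real_, p = NA_real_, aic = NA_real_))
      }
      i <- match(which_term, fit$pooled$term)
      c(hr = exp(fit$pooled$coef[i]), p = fit$pooled$p[i], aic = fit$aic)
    }
    s <- pick(single, pr)
    a <- pick(adjusted, pr)
    if (inherits(single, "error")) {
      note <- paste(note, "single-model fit failed:",
                    conditionMessage(single))
    }
    if (inherits(adjusted, "error")) {
      note <- paste(note, "adjusted-model fit failed:",
                    conditionMessage(adjusted))
    }
    data.frame(
      predictor = pr,
      hr_single = s[["hr"]], p_single = s[["p"]], aic_single = s[["aic"]],
      hr_adjusted = a[["hr"]], p_adjusted = a[["p"]],
      aic_adjusted = a[["aic"]],
      note = trimws(note)
    )
  })
  do.call(rbind, rows)
}

#' Backward elimination for a multivariable Cox model
#'
#' Candidates are first screened univariably: only terms with Wald
#' p < `enter_alpha` enter the initial multivariable model. Elimination then
#' repeatedly removes the term with the largest Wald p until every remaining
#' term has p < `stay_alpha`. Ties (equal p) remove the term declared later
#' in `candidates`, so the procedure is deterministic for a fixed dataset.
#'
#' @param data a complete data.frame (impute first if needed).
#' @param candidates character vector of candidate terms, each a numeric or
#'   0/1 column.
#' @param enter_alpha univariable screening level (default 0.10).
#' @param stay_alpha retention level (default 0.05).
#' @param time_col,event_col survival columns.
#' @return list with `model` (a `cox_model`, or `NULL` if no term
#'   survives), `selected`, `screened_out`, `elimination_path`
#'   (data.frame step/term/p) and `status`.
#' @export
backward_eliminate <- function(data, candidates,
                               enter_alpha = 0.10, stay_alpha = 0.05,
                               time_col = "time_composite_years",
                               event_col = "event_composite") {
  stopifnot(length(candidates) >= 1)
  uni_p <- vapply(candidates, function(tr) {
    fit <- tryCatch(
      fit_cox(data, tr, time_col = time_col, event_col = event_col),
      error = function(e) NULL
    )
    if (is.null(fit)) NA_real_ else min(fit$terms$p)
  }, numeric(1))
  current <- candidates[!is.na(uni_p) & uni_p < enter_alpha]
  screened_out <- setdiff(candidates, current)
  path <- data.frame(step = integer(), term = character(), p = numeric())
  step <- 0L
  while (length(current) > 0) {
    fit <- fit_cox(data, current, time_col = time_col, event_col = event_col)
    # per-candidate p: worst (largest) p among the coefficients it generated
    term_p <- vapply(current, function(tr) {
      max(fit$terms$p[startsWith(fit$terms$term, tr)])
    }, numeric(1))
    worst <- max(term_p)
    if (worst < stay_alpha) break
    # ties: remove the later term in declared candidate order
    at_max <- which(term_p == worst)
    drop_term <- current[at_max[length(at_max)]]
    step <- step + 1L
    path <- rbind(path, data.frame(step = step, term = drop_term, p = worst))
    current <- setdiff(current, drop_term)
  }
  if (length(current) == 0) {
    return(list(model = NULL, selected = character(),
                screened_out = screened_out, elimination_path = path,
                status = "no candidate retained"))
  }
  list(
    model = fit_cox(data, current, time_col = time_col,
                    event_col = event_col),
    selected = current, screened_out = screened_out,
    elimination_path = path, status = "ok"
  )
}
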