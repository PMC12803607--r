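#' Multiple imputation by bootstrap plus predictive mean matching
#'
#' For each of `m` imputations: draw a bootstrap sample of the records;
#' for each incomplete variable (visited in order of increasing
#' missingness), fit a linear predictor from the other imputation variables
#' on the bootstrap rows where the target is observed; predict for all
#' original rows; and fill each missing value with the observed value of a
#' donor drawn at random from the `donors` nearest predicted-mean
#' neighbours among the observed cases. The bootstrap propagates parameter
#' uncertainty; predictive mean matching guarantees every imputed value is
#' an actually observed value of that variable, so categorical and bounded
#' variables stay valid by construction (they are matched on their numeric
#' predicted score).
#'
#' Missing predictor entries are initialised with random draws from the
#' observed values and updated as the chained pass proceeds; `n_passes`
#' controls how many sweeps over the variables are made per imputation.
#'
#' @param records data.frame.
#' @param variables the imputation variables (default: the eight-variable
#'   set used for the prognostic models — CVF, age, BMI, LVEF,
#'   log NT-proBNP, NYHA class, creatinine, diabetes).
#' @param m number of imputed datasets (default 50).
#' @param donors donor-pool size for predictive mean matching (default 5).
#' @param n_passes chained sweeps per imputation (default 1).
#' @param seed integer seed.
#' @return An object of class `imputation_result`: list with `datasets`
#'   (list of `m` complete data.frames), `m`, `variables`,
#'   `n_missing` (per variable).
#' @export
impute_pmm_bootstrap <- function(records,
                                 variables = c("cvf_percent", "age", "bmi",
                                               "lvef", "log_ntprobnp",
                                               "nyha", "creatinine",
                                               "diabetes"),
                                 m = 50, donors = 5, n_passes = 1,
                                 seed = 1L) {
  stopifnot(is.data.frame(records))
  if (m < 2) stop("`m` must be >= 2")
  if (donors < 1) stop("`donors` must be >= 1")
  missing_vars <- setdiff(variables, names(records))
  if (length(missing_vars)) {
    stop("records lack imputation variables: ",
         paste(missing_vars, collapse = ", "))
  }
  n_miss <- vapply(variables, function(v) sum(is.na(records[[v]])),
                   numeric(1))
  if (any(n_miss == nrow(records))) {
    stop("variable with zero observed values: ",
         paste(variables[n_miss == nrow(records)], collapse = ", "))
  }
  incomplete <- variables[n_miss > 0]
  # visit order: least missing first, so later fits see better predictors
  incomplete <- incomplete[order(n_miss[incomplete])]
  seed <- check_seed(seed)

  datasets <- withr::with_seed(seed, {
    lapply(seq_len(m), function(i) {
      out <- records
      if (length(incomplete) == 0) return(out)
      boot_idx <- sample.int(nrow(records), replace = TRUE)
      # working copy: initialise NAs by random observed draws
      work <- records
      for (v in variables) {
        na_i <- is.na(work[[v]])
        if (any(na_i)) {
          obs <- work[[v]][!na_i]
          work[[v]][na_i] <- sample(obs, sum(na_i), replace = TRUE)
        }
      }
      for (pass in seq_len(n_passes)) {
        for (v in incomplete) {
          preds <- setdiff(variables, v)
          boot <- work[boot_idx, , drop = FALSE]
          # fit only on bootstrap rows where the target is truly observed
          boot_obs <- !is.na(records[[v]][boot_idx])
          f <- as.formula(paste(v, "~", paste(preds, collapse = " + ")))
          fit <- lm(f, data = boot[boot_obs, , drop = FALSE])
          yhat <- predict(fit, newdata = work)
          obs_i <- which(!is.na(records[[v]]))
          mis_i <- which(is.na(records[[v]]))
          for (j in mis_i) {
            d <- abs(yhat[obs_i] - yhat[j])
            pool <- obs_i[order(d)][seq_len(min(donors, length(obs_i)))]
            donor <- pool[sample.int(length(pool), 1)]
            work[[v]][j] <- records[[v]][donor]
          }
        }
      }
      for (v in incomplete) out[[v]] <- work[[v]]
      out
    })
  })
  structure(
    list(datasets = datasets, m = m, variables = variables,
         n_missing = n_miss, donors = donors),
    class = "imputation_result"
  )
}

#' @export
print.imputation_result <- function(x, ...) {
  cat(sprintf("<imputation_result> m=%d, %d variable(s), %d with missing\n",
              x$m, length(x$variables), sum(x$n_missing > 0)))
  invisible(x)
}

#' Pool estimates across imputations by Rubin's rules
#'
#' Pooled coefficient is the mean across imputations; total variance is
#' `W + (1 + 1/m) B` with `W` the mean within-imputation variance and `B`
#' the between-imputation variance. Degrees of freedom follow
#' Barnard-Rubin when a complete-data df `nu_com` is supplied, otherwise
#' the classic large-sample `(m - 1)(1 + 1/r)^2`.
#'
#' @param per_imputation_fits list of >= 2 data.frames each with columns
#'   `term`, `coef`, `se` and identical term sets (e.g. the `terms` slot of
#'   [fit_cox()] results).
#' @param nu_com optional complete-data degrees of freedom.
#' @return data.frame with `term`, `coef`, `se`, `df`, `p`,
#'   `ci_lo`, `ci_hi` (on the coefficient scale), `b_between`, `w_within`.
#' @export
pool_rubin <- function(per_imputation_fits, nu_com = Inf) {
  m <- length(per_imputation_fits)
  if (m < 2) stop("need >= 2 imputation fits to pool")
  terms <- per_imputation_fits[[1]]$term
  for (f in per_imputation_fits) {
    if (!identical(f$term, terms)) stop("mismatched term sets across fits")
  }
  coefs <- sapply(per_imputation_fits, function(f) f$coef)
  ses <- sapply(per_imputation_fits, function(f) f$se)
  if (is.null(dim(coefs))) {
    coefs <- matrix(coefs, nrow = 1)
    ses <- matrix(ses, nrow = 1)
  }
  qbar <- rowMeans(coefs)
  W <- rowMeans(ses^2)
  B <- apply(coefs, 1, var)
  Tv <- W + (1 + 1 / m) * B
  r <- (1 + 1 / m) * B / W
  df_large <- ifelse(B > 0, (m - 1) * (1 + 1 / r)^2, Inf)
  df <- df_large
  if (is.finite(nu_com)) {
    lambda <- (1 + 1 / m) * B / Tv
    df_obs <- (nu_com + 1) / (nu_com + 3) * nu_com * (1 - lambda)
    df <- 1 / (1 / df_large + 1 / df_obs)
  }
  se <- sqrt(Tv)
  stat <- qbar / se
  p <- 2 * pt(-abs(stat), df = pmax(df, 1))
  tcrit <- qt(0.975, df = pmax(df, 1))
  data.frame(
    term = terms, coef = qbar, se = se, df = df, p = p,
    ci_lo = qbar - tcrit * se, ci_hi = qbar + tcrit * se,
    b_between = B, w_within = W, row.names = NULL
  )
}
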