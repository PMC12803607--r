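#' Calibrate a log-normal distribution to a printed median and IQR
#'
#' Sets `mu = log(median)` and chooses `sigma` so the theoretical quartile
#' ratio matches: `sigma = log(q3/q1) / (2 * qnorm(0.75))`. A printed
#' median and IQR can be jointly inconsistent with any log-normal; the
#' median and the IQR *ratio* are matched exactly, and the implied quartiles
#' plus a log-asymmetry diagnostic (`log(q3/median) - log(median/q1)`) are
#' reported so the mismatch is visible.
#'
#' @param median,q1,q3 positive reals with `q1 < median < q3`.
#' @return list with `mu`, `sigma`, `implied_q1`, `implied_q3`,
#'   `log_asymmetry`.
#' @examples
#' calibrate_lognormal(655, 218, 2253)$sigma
#' @export
calibrate_lognormal <- function(median, q1, q3) {
  if (!(q1 < median && median < q3) || q1 <= 0) {
    stop("need 0 < q1 < median < q3")
  }
  mu <- log(median)
  sigma <- log(q3 / q1) / (2 * qnorm(0.75))
  z <- qnorm(0.75)
  list(
    mu = mu, sigma = sigma,
    implied_q1 = exp(mu - z * sigma),
    implied_q3 = exp(mu + z * sigma),
    log_asymmetry = log(q3 / median) - log(median / q1)
  )
}

#' Specification of a synthetic DCM survival cohort
#'
#' Defaults reproduce the marginal covariate structure of a tertiary-centre
#' dilated-cardiomyopathy cohort: age ~ N(54.0, 13.4) years, BMI ~
#' N(27.1, 5.7), LVEF ~ N(31.3, 12.5) truncated to (5, 70) %, NT-proBNP
#' log-normal calibrated to median 655 ng/L with IQR 218–2253, serum
#' creatinine log-normal with natural-scale mean 1.0 and SD 0.6 mg/dl,
#' diabetes ~ Bernoulli(0.176), NYHA class ~ categorical(0.403, 0.256,
#' 0.171, 0.171). CVF ~ N(32, 15) truncated to \[0, 100\] unless supplied
#' externally. Event times follow a Weibull proportional-hazards model whose
#' log-hazard contains a change-point effect of CVF at `tau_true` plus a
#' log-NT-proBNP effect; the two endpoints (composite heart-failure event,
#' all-cause death) arise from correlated latent times sharing a normal
#' frailty on the log-hazard. Follow-up is right-censored by exponential
#' dropout and administratively at `max_followup_years`.
#'
#' @param n cohort size (default 524).
#' @param beta_cvf log hazard ratio of the CVF change-point indicator
#'   `1[CVF > tau_true]` (default `log(3)`).
#' @param tau_true true CVF change-point in percent, inside (5, 95).
#' @param beta_bnp log hazard ratio per unit of centred log NT-proBNP.
#' @param weibull_shape shape of the baseline Weibull hazard.
#' @param scale_composite,scale_death baseline Weibull scales (years) of the
#'   latent heart-failure event time and death time.
#' @param frailty_sd SD of the shared normal frailty linking the endpoints.
#' @param max_followup_years administrative censoring horizon (default 8).
#' @param dropout_rate exponential dropout rate per year.
#' @param missing_rates named list of MCAR missingness rates in \[0, 1) for
#'   covariate columns (see [inject_missingness()]).
#' @param seed integer seed.
#' @return list of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 524,
                        beta_cvf = log(3), tau_true = 32,
                        beta_bnp = log(1.38),
                        weibull_shape = 1.2,
                        scale_composite = 400, scale_death = 55,
                        frailty_sd = 0.3,
                        max_followup_years = 8, dropout_rate = 0.16,
                        missing_rates = list(), seed = 1L) {
  if (n <= 0) stop("`n` must be > 0")
  if (tau_true <= 5 || tau_true >= 95) stop("`tau_true` must lie in (5, 95)")
  if (max_followup_years <= 0) stop("`max_followup_years` must be > 0")
  rates <- unlist(missing_rates)
  if (length(rates) && (any(rates < 0) || any(rates >= 1))) {
    stop("missingness rates must lie in [0, 1)")
  }
  structure(
    list(
      n = as.integer(n), beta_cvf = beta_cvf, tau_true = tau_true,
      beta_bnp = beta_bnp, weibull_shape = weibull_shape,
      scale_composite = scale_composite, scale_death = scale_death,
      frailty_sd = frailty_sd, max_followup_years = max_followup_years,
      dropout_rate = dropout_rate, missing_rates = missing_rates,
      seed = check_seed(seed)
    ),
    class = "cohort_spec"
  )
}

rnorm_trunc <- function(n, mean, sd, lo, hi) {
  p_lo <- pnorm(lo, mean, sd)
  p_hi <- pnorm(hi, mean, sd)
  qnorm(runif(n, p_lo, p_hi), mean, sd)
}

#' Simulate a patient-level survival cohort
#'
#' Draws covariates, latent Weibull proportional-hazards event times by
#' inverse-transform sampling, applies censoring and optional MCAR
#' missingness per the spec. Both endpoints carry their own observation
#' time: the composite endpoint stops at the first heart-failure event or
#' death, all-cause mortality at death.
#'
#' @param spec a [cohort_spec()].
#' @param cvf_percent optional externally measured CVF values (length `n`),
#'   e.g. from the image-quantification stage; otherwise drawn from the
#'   spec's truncated-normal CVF model.
#' @return data.frame with one row per patient: `id`, covariates (`age`,
#'   `bmi`, `lvef`, `ntprobnp`, `log_ntprobnp`, `creatinine`, `diabetes`,
#'   `nyha`, `cvf_percent`), `time_composite_years`, `event_composite`,
#'   `time_death_years`, `event_death_any`.
#' @export
simulate_cohort <- function(spec, cvf_percent = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n
  bnp_cal <- calibrate_lognormal(655, 218, 2253)
  # creatinine: match natural-scale mean 1.0 / SD 0.6 by moments
  cr_sigma2 <- log(1 + 0.6^2 / 1.0^2)
  cr_mu <- log(1.0) - cr_sigma2 / 2

  df <- withr::with_seed(spec$seed, {
    age <- rnorm(n, 54.0, 13.4)
    bmi <- rnorm(n, 27.1, 5.7)
    lvef <- rnorm_trunc(n, 31.3, 12.5, 5, 70)
    log_bnp <- rnorm(n, bnp_cal$mu, bnp_cal$sigma)
    creat <- exp(rnorm(n, cr_mu, sqrt(cr_sigma2)))
    diabetes <- rbinom(n, 1, 0.176)
    nyha <- sample(1:4, n, replace = TRUE,
                   prob = c(0.403, 0.256, 0.171, 0.171))
    cvf <- if (is.null(cvf_percent)) {
      rnorm_trunc(n, 32, 15, 0, 100)
    } else {
      if (length(cvf_percent) != n) stop("`cvf_percent` must have length n")
      cvf_percent
    }

    frailty <- rnorm(n, 0, spec$frailty_sd)
    lp <- spec$beta_cvf * (cvf > spec$tau_true) +
      spec$beta_bnp * (log_bnp - bnp_cal$mu) + frailty

    # inverse-transform Weibull PH: S(t|x) = exp(-(t/lambda)^k e^lp)
    draw_time <- function(lambda) {
      u <- runif(n)
      lambda * (-log(u) * exp(-lp))^(1 / spec$weibull_shape)
    }
    t_hf <- draw_time(spec$scale_composite)
    t_death <- draw_time(spec$scale_death)
    t_comp <- pmin(t_hf, t_death)

    cens <- pmin(spec$max_followup_years,
                 if (spec$dropout_rate > 0) rexp(n, spec$dropout_rate)
                 else Inf)

    data.frame(
      id = sprintf("P%04d", seq_len(n)),
      age = age, bmi = bmi, lvef = lvef,
      ntprobnp = exp(log_bnp), log_ntprobnp = log_bnp,
      creatinine = creat, diabetes = diabetes, nyha = nyha,
      cvf_percent = cvf,
      time_composite_years = pmin(t_comp, cens),
      event_composite = as.integer(t_comp <= cens),
      time_death_years = pmin(t_death, cens),
      event_death_any = as.integer(t_death <= cens)
    )
  })
  if (length(spec$missing_rates)) {
    df <- inject_missingness(df, spec$missing_rates,
                             seed = spec$seed + 104729L)
  }
  df
}

#' Delete covariate values completely at random
#'
#' Creates the missing-data problem that multiple imputation solves: each
#' named covariate loses values independently at its stated rate. Follow-up
#' times and event indicators can never be made missing.
#'
#' @param records cohort data.frame.
#' @param rates named list/vector of rates in \[0, 1).
#' @param seed integer seed.
#' @return the records with `NA`s injected.
#' @export
inject_missingness <- function(records, rates, seed = 1L) {
  stopifnot(is.data.frame(records))
  seed <- check_seed(seed)
  rates <- unlist(rates)
  protected <- c("time_composite_years", "event_composite",
                 "time_death_years", "event_death_any", "id")
  bad <- intersect(names(rates), protected)
  if (length(bad)) {
    stop("follow-up time and event fields can never be missing: ",
         paste(bad, collapse = ", "))
  }
  unknown <- setdiff(names(rates), names(records))
  if (length(unknown)) stop("unknown columns: ", paste(unknown, collapse = ", "))
  if (any(rates < 0 | rates >= 1)) stop("rates must lie in [0, 1)")
  withr::with_seed(seed, {
    for (v in names(rates)) {
      if (rates[[v]] == 0) next
      hit <- runif(nrow(records)) < rates[[v]]
      records[[v]][hit] <- NA
    }
  })
  records
}
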