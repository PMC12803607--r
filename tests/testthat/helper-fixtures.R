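# shared fixtures and independent oracles, all built in code at test time

default_pal <- fibrosurv::stain_palette("trichrome")

small_slide <- function(cvf = 30, area = 0.3, seed = 11) {
  generate_fragment(area, cvf, default_pal, seed = seed)
}

trained_clf <- function(slide, n = 200, seed = 21) {
  train_classifier(sample_training_pixels(slide, n, seed = seed))
}

# brute-force Gaussian log-posterior classifier (shared covariance):
# independent of the package's discriminant shortcut, same documented
# tie rule (first class in order wins, ties up to a tiny tolerance)
oracle_classify <- function(X, clf) {
  Sinv <- solve(clf$shared_covariance)
  out <- integer(nrow(X))
  codes <- c(background = 0L, muscle = 1L, fibrosis = 2L)
  for (i in seq_len(nrow(X))) {
    lps <- vapply(clf$classes, function(k) {
      d <- X[i, ] - clf$class_means[[k]]
      -0.5 * drop(t(d) %*% Sinv %*% d) + log(clf$priors[[k]])
    }, numeric(1))
    m <- max(lps)
    tol <- 1e-9 * (1 + abs(m))
    out[i] <- codes[[clf$classes[which(lps >= m - tol)[1]]]]
  }
  out
}

# naive risk-set enumeration of KM and the two-group log-rank statistic
oracle_km <- function(times, events) {
  ut <- sort(unique(times[events == 1]))
  s <- 1
  surv <- numeric(length(ut))
  for (j in seq_along(ut)) {
    n_risk <- sum(times >= ut[j])
    d <- sum(events[times == ut[j]])
    s <- s * (1 - d / n_risk)
    surv[j] <- s
  }
  list(time = ut, survival = surv)
}

oracle_logrank <- function(times, events, g1) {
  ut <- sort(unique(times[events == 1]))
  U <- 0; V <- 0; O1 <- 0; E1 <- 0
  for (tj in ut) {
    at_risk <- times >= tj
    n <- sum(at_risk); n1 <- sum(at_risk & g1)
    d <- sum(events[times == tj]); d1 <- sum(events[times == tj & g1])
    e1 <- n1 * d / n
    U <- U + d1 - e1
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    O1 <- O1 + d1; E1 <- E1 + e1
  }
  list(chi = U^2 / V, U = U, V = V, O1 = O1, E1 = E1)
}

class_mm2_test <- function(seg, cls) {
  seg$areas$mm2[seg$areas$class == cls]
}

# small survival cohort for model-level tests
sim_small_cohort <- function(n = 300, seed = 1, ...) {
  simulate_cohort(cohort_spec(n = n, seed = seed, ...))
}
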