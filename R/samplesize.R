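#' Power of a Bland-Altman agreement study
#'
#' Probability that both 95% limit-of-agreement confidence bounds fall inside
#' the clinical agreement band `(-delta, delta)`, for `n` paired differences
#' distributed Normal(`bias`, `sd`^2). The LoA confidence interval uses the
#' classic approximate standard error `s * sqrt(3/n)` with the two-sided t
#' quantile. The joint probability is computed exactly: conditional on the
#' sample SD the two one-sided conditions are normal in the sample mean, and
#' the result is integrated over the chi distribution of the sample SD (the
#' per-side conditions alone are noncentral-t probabilities).
#'
#' @param n Number of paired measurements (>= 3).
#' @param sd True SD of the differences.
#' @param delta Clinically acceptable agreement limit (same units).
#' @param bias Assumed true bias (default 0).
#' @param alpha Significance level of the LoA confidence intervals.
#' @return Probability in `[0, 1]`.
#' @export
ba_agreement_power <- function(n, sd, delta, bias = 0, alpha = 0.05) {
  stopifnot(n >= 3, sd > 0, delta > 0, alpha > 0, alpha < 1)
  z <- stats::qnorm(0.975)
  if (delta <= z * sd + abs(bias)) return(0)
  df <- n - 1
  cc <- z + stats::qt(1 - alpha / 2, df) * sqrt(3 / n)
  integrand <- function(s) {
    (stats::pnorm((delta - cc * s - bias) * sqrt(n) / sd) -
       stats::pnorm((-delta + cc * s - bias) * sqrt(n) / sd)) *
      stats::dchisq(df * s^2 / sd^2, df) * 2 * df * s / sd^2
  }
  stats::integrate(integrand, 0, delta / cc, rel.tol = 1e-9)$value
}

#' Bland-Altman sample size (Lu 2016 procedure)
#'
#' Smallest number of paired measurements for which the probability that both
#' 95% LoA confidence bounds fall inside the clinical agreement band reaches
#' the requested power ([ba_agreement_power()]). Monotone: decreasing in
#' `delta`, increasing in `power`.
#'
#' @param sd Assumed SD of the differences between the two methods.
#' @param delta Clinically acceptable agreement limit.
#' @param alpha Significance level (default 0.05).
#' @param power Required power (default 0.80).
#' @param bias Assumed true bias (default 0).
#' @param n_max Search cap.
#' @return Integer sample size (minimum 3).
#' @export
ba_sample_size <- function(sd, delta, alpha = 0.05, power = 0.80, bias = 0,
                           n_max = 1e6L) {
  stopifnot(sd > 0, delta > 0, alpha > 0, alpha < 1, power > 0, power < 1)
  z <- stats::qnorm(0.975)
  if (delta <= z * sd + abs(bias))
    stop(sprintf(paste("unattainable specification: delta (%.3f) must exceed",
                       "1.96*sd + |bias| = %.3f"), delta, z * sd + abs(bias)))
  n <- 3L
  while (n <= n_max) {
    if (ba_agreement_power(n, sd, delta, bias, alpha) >= power) return(n)
    n <- n + 1L
  }
  stop("no sample size up to n_max reaches the requested power")
}

#' Monte-Carlo check of the Bland-Altman containment probability
#'
#' Simulates `nsim` studies of `n` normal differences and reports the
#' fraction in which both LoA confidence bounds (approximate construction,
#' as in [ba_agreement_power()]) fall inside `(-delta, delta)`.
#'
#' @inheritParams ba_agreement_power
#' @param nsim Number of simulated studies.
#' @param seed Integer seed.
#' @return Empirical containment probability.
#' @export
ba_power_mc <- function(n, sd, delta, bias = 0, alpha = 0.05,
                        nsim = 10000L, seed = 1L) {
  z <- stats::qnorm(0.975)
  df <- n - 1
  tq <- stats::qt(1 - alpha / 2, df)
  with_seed(seed, {
    dbar <- stats::rnorm(nsim, bias, sd / sqrt(n))
    s <- sd * sqrt(stats::rchisq(nsim, df) / df)
    half <- z * s + tq * s * sqrt(3 / n)
    mean(dbar + half < delta & dbar - half > -delta)
  })
}

#' Patients needed for a given number of measurements
#'
#' Converts a required number of measurements into a patient count when each
#' patient contributes both hips and a subset of patients is measured on
#' extra occasions: the re-reads of `n_triple_read_patients` patients
#' contribute `2 extra reads x hips` measurements each, and the remainder is
#' divided over the hips per patient (rounded up).
#'
#' @param n_measurements Required measurements (e.g. from [ba_sample_size()]).
#' @param hips_per_patient Measurements per patient per occasion (default 2).
#' @param n_triple_read_patients Patients measured three times (default 5).
#' @return Integer number of patients.
#' @export
patients_from_measurements <- function(n_measurements, hips_per_patient = 2L,
                                       n_triple_read_patients = 5L) {
  stopifnot(n_measurements > 0, hips_per_patient > 0,
            n_triple_read_patients >= 0)
  extra <- n_triple_read_patients * 2L * hips_per_patient
  if (extra >= n_measurements)
    stop("re-read measurements alone exceed the required total")
  as.integer(ceiling((n_measurements - extra) / hips_per_patient))
}
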