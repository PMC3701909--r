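#' Construct a dwell sample
#'
#' Durations of bound-state events with right-censoring flags. A censored
#' event touched the start or end of the movie, so its true duration is at
#' least the recorded one.
#'
#' @param durations Event durations, seconds (>= 0; uncensored events must
#'   be positive).
#' @param censored Logical vector, same length.
#' @param source Label (cell id, condition, ...).
#' @return Data frame of class `dwell_sample` with columns `duration_s`,
#'   `censored`, `source`.
#' @export
dwell_sample <- function(durations, censored = rep(FALSE, length(durations)),
                         source = "unknown") {
  if (length(durations) != length(censored)) {
    stop_smkin("durations and censored must have equal length", "smkin_schema")
  }
  if (any(durations < 0) || any(durations[!censored] <= 0)) {
    stop_smkin("uncensored durations must be positive", "smkin_schema")
  }
  structure(data.frame(duration_s = as.numeric(durations),
                       censored = as.logical(censored),
                       source = if (length(durations)) source
                                else character(0)),
            class = c("dwell_sample", "data.frame"))
}

#' Exponential mean of a dwell sample
#'
#' Observed dwell-time distributions are close to exponential,
#' `f(t) = (1/mean) * exp(-t/mean)`, so the maximum-likelihood estimate of
#' the mean is the sample mean of completed dwells (`censor_policy =
#' "exclude"`, the default) or the censoring-corrected ratio
#' `sum(all durations) / n_uncensored` (`"survival_mle"`). The SEM of an
#' exponential mean is `mean / sqrt(n)` with `n` the number of uncensored
#' events.
#'
#' @param sample A [dwell_sample()].
#' @param censor_policy `"exclude"` or `"survival_mle"`.
#' @param t_min Detection dead time, seconds (default 0): events shorter
#'   than `t_min` cannot be resolved by the upstream classifier, so they
#'   are dropped and `t_min` is subtracted from the surviving durations,
#'   which leaves the estimate unbiased for an exponential (memoryless)
#'   dwell distribution.
#' @return List with `mean`, `sem` (seconds) and `n` (uncensored events
#'   used).
#' @examples
#' s <- dwell_sample(c(2, 4, 6), c(FALSE, FALSE, FALSE))
#' fit_exponential_mean(s)
#' @export
fit_exponential_mean <- function(sample,
                                 censor_policy = c("exclude", "survival_mle"),
                                 t_min = 0) {
  stopifnot(inherits(sample, "dwell_sample"))
  censor_policy <- match.arg(censor_policy)
  keep <- sample$duration_s >= t_min
  d <- sample$duration_s[keep] - t_min
  cens <- sample$censored[keep]
  if (censor_policy == "exclude") {
    d <- d[!cens]
    cens <- cens[!cens]
  }
  n_unc <- sum(!cens)
  if (n_unc == 0L) {
    stop_smkin("no uncensored dwell events (at or above t_min)",
               "smkin_no_events")
  }
  m <- sum(d) / n_unc
  list(mean = m, sem = m / sqrt(n_unc), n = n_unc)
}

#' Photobleaching rate from lifetimes or a decay curve
#'
#' Either a maximum-likelihood exponential fit to single-fluorophore
#' lifetimes (a [dwell_sample()], censoring handled by the survival MLE) or
#' a log-linear least-squares fit of a background-subtracted, normalized
#' decay curve `f(t) = k_bl * exp(-k_bl * t)`.
#'
#' @param bleach_sample A [dwell_sample()] of lifetimes, or a data frame /
#'   list with `t_s` and `value` giving a decay curve.
#' @return List with `k_bl` (1/s), `tau_bl` (s) and `tau_bl_sem`
#'   (s; `NA` for curve fits).
#' @export
fit_bleach_rate <- function(bleach_sample) {
  if (inherits(bleach_sample, "dwell_sample")) {
    n_unc <- sum(!bleach_sample$censored)
    if (n_unc == 0L) stop_smkin("no uncensored lifetimes", "smkin_no_events")
    tau <- sum(bleach_sample$duration_s) / n_unc
    return(list(k_bl = 1 / tau, tau_bl = tau, tau_bl_sem = tau / sqrt(n_unc)))
  }
  t_s <- bleach_sample$t_s
  value <- bleach_sample$value
  if (is.null(t_s) || is.null(value) || length(t_s) < 3L) {
    stop_smkin("decay curve needs t_s and value with >= 3 points",
               "smkin_invalid_parameter")
  }
  keep <- value > 0
  if (sum(keep) < 3L) stop_smkin("decay curve not positive", "smkin_fit_failure")
  fit <- stats::lm(log(value[keep]) ~ t_s[keep])
  k <- -unname(stats::coef(fit)[2L])
  if (!is.finite(k) || k <= 0) {
    stop_smkin("curve does not decay: fitted rate is not positive",
               "smkin_fit_failure")
  }
  list(k_bl = k, tau_bl = 1 / k, tau_bl_sem = NA_real_)
}

#' Photobleach correction of an observed dwell time
#'
#' Unbinding and photobleaching both terminate an observed dwell, so the
#' observed mean dwell time is `tau_obs = (1/tau_off + 1/tau_bl)^-1`
#' (the minimum of two independent exponential clocks). Given an
#' independently measured mean bleaching time `tau_bl`, the molecular off
#' time is recovered as
#' `tau_off = (1/tau_obs - 1/tau_bl)^-1`,
#' defined only while `tau_obs < tau_bl`. The SEM is first-order (delta
#' method) over both inputs:
#' `var(tau_off) = (d tau_off/d tau_obs)^2 var(tau_obs) +
#'  (d tau_off/d tau_bl)^2 var(tau_bl)` with
#' `d tau_off/d tau_obs = (tau_off/tau_obs)^2` and
#' `d tau_off/d tau_bl = -(tau_off/tau_bl)^2`.
#'
#' @param tau_obs Observed mean dwell time, s.
#' @param tau_obs_sem Its SEM, s.
#' @param tau_bl Mean photobleaching time, s (may be `Inf`).
#' @param tau_bl_sem Its SEM, s (default 0).
#' @return List with `tau_off` and `tau_off_sem`, seconds.
#' @examples
#' correct_dwell_time(4.432, 0.05, 30)  # ~5.2 s
#' @export
correct_dwell_time <- function(tau_obs, tau_obs_sem = 0, tau_bl = Inf,
                               tau_bl_sem = 0) {
  if (!is.numeric(tau_obs) || tau_obs <= 0) {
    stop_smkin("tau_obs must be positive", "smkin_invalid_parameter")
  }
  if (tau_bl <= 0) stop_smkin("tau_bl must be positive",
                              "smkin_invalid_parameter")
  if (tau_obs >= tau_bl) {
    stop_smkin(
      "tau_obs >= tau_bl: bleaching-dominated data, off time undefined",
      "smkin_undefined_correction")
  }
  inv <- 1 / tau_obs - 1 / tau_bl
  tau_off <- 1 / inv
  d_obs <- (tau_off / tau_obs)^2
  d_bl <- if (is.finite(tau_bl)) (tau_off / tau_bl)^2 else 0
  sem <- sqrt((d_obs * tau_obs_sem)^2 + (d_bl * tau_bl_sem)^2)
  list(tau_off = tau_off, tau_off_sem = sem)
}

#' Observed dwell-time density under competing unbinding and bleaching
#'
#' `f(t) = (1/tau_bl + 1/tau_off) * exp(-t * (1/tau_bl + 1/tau_off))`: an
#' exponential whose rate is the sum of the unbinding and bleaching rates.
#'
#' @param t Time(s), seconds, >= 0 (vectorized).
#' @param tau_off Molecular off time, s (> 0).
#' @param tau_bl Mean bleaching time, s (> 0, may be `Inf`).
#' @return Density values, 1/s.
#' @export
dwell_pdf <- function(t, tau_off, tau_bl = Inf) {
  if (tau_off <= 0 || tau_bl <= 0) {
    stop_smkin("time scales must be positive", "smkin_invalid_parameter")
  }
  rate <- 1 / tau_off + (if (is.finite(tau_bl)) 1 / tau_bl else 0)
  stats::dexp(t, rate = rate)
}

#' Full kinetic estimate from a dwell sample and a bleach measurement
#'
#' Convenience wrapper running [fit_exponential_mean()] on the dwell sample
#' and [correct_dwell_time()] against the bleaching time, optionally with a
#' bootstrap SEM for small samples.
#'
#' @param sample A [dwell_sample()] of observed dwells.
#' @param tau_bl,tau_bl_sem Mean bleaching time and SEM, seconds.
#' @param censor_policy,t_min Passed to [fit_exponential_mean()].
#' @param bootstrap If `TRUE`, replace the delta-method SEM of `tau_off`
#'   with the SD over `n_boot` nonparametric resamples.
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Seed for the bootstrap.
#' @return Object of class `kinetic_estimate`: `tau_obs_mean`,
#'   `tau_obs_sem`, `tau_bl`, `tau_bl_sem`, `tau_off`, `tau_off_sem`,
#'   `n_events`.
#' @export
estimate_kinetics <- function(sample, tau_bl, tau_bl_sem = 0,
                              censor_policy = "exclude", t_min = 0,
                              bootstrap = FALSE, n_boot = 1000L,
                              seed = NULL) {
  obs <- fit_exponential_mean(sample, censor_policy, t_min = t_min)
  corr <- correct_dwell_time(obs$mean, obs$sem, tau_bl, tau_bl_sem)
  if (bootstrap) {
    keep <- if (censor_policy == "exclude") !sample$censored
            else rep(TRUE, nrow(sample))
    d <- sample$duration_s[keep]
    cns <- sample$censored[keep]
    boots <- with_seed(seed, vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(length(d), replace = TRUE)
      m <- if (censor_policy == "exclude") mean(d[idx])
           else sum(d[idx]) / max(1L, sum(!cns[idx]))
      if (m >= tau_bl) NA_real_ else 1 / (1 / m - 1 / tau_bl)
    }, numeric(1)))
    corr$tau_off_sem <- stats::sd(boots, na.rm = TRUE)
  }
  structure(list(tau_obs_mean = obs$mean, tau_obs_sem = obs$sem,
                 tau_bl = tau_bl, tau_bl_sem = tau_bl_sem,
                 tau_off = corr$tau_off, tau_off_sem = corr$tau_off_sem,
                 n_events = obs$n),
            class = "kinetic_estimate")
}

#' @export
print.kinetic_estimate <- function(x, ...) {
  cat(sprintf(
    "<kinetic_estimate> tau_obs = %.3g +/- %.2g s (n = %d), tau_bl = %.3g s -> tau_off = %.3g +/- %.2g s\n",
    x$tau_obs_mean, x$tau_obs_sem, x$n_events, x$tau_bl,
    x$tau_off, x$tau_off_sem))
  invisible(x)
}

#' Compare two dwell-time conditions
#'
#' Reports the difference of corrected off times (or observed means) with
#' the combined SEM `sqrt(sem1^2 + sem2^2)`. No hypothesis test is
#' attached.
#'
#' @param est1,est2 `kinetic_estimate` objects.
#' @return List with `delta_tau_off` and `sem`.
#' @export
compare_dwell_conditions <- function(est1, est2) {
  stopifnot(inherits(est1, "kinetic_estimate"),
            inherits(est2, "kinetic_estimate"))
  list(delta_tau_off = est1$tau_off - est2$tau_off,
       sem = sqrt(est1$tau_off_sem^2 + est2$tau_off_sem^2))
}
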