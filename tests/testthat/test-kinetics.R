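# Dwell-time kinetics: exponential fits, photobleach correction, pdf.

test_that("the exponential mean MLE recovers simulated dwells", {
  expected <- 1 / (1 / 5.2 + 1 / 30)                  # 4.43 s
  withr::with_seed(1, {
    s <- dwell_sample(stats::rexp(10000L, 1 / expected))
  })
  fit <- fit_exponential_mean(s)
  expect_lt(abs(fit$mean - expected), 3 * expected / sqrt(10000))
  expect_equal(fit$sem, fit$mean / sqrt(10000))
})

test_that("degenerate dwell samples behave as documented", {
  s <- dwell_sample(rep(7, 5))
  expect_equal(fit_exponential_mean(s)$mean, 7)
  all_cens <- dwell_sample(rep(3, 4), rep(TRUE, 4))
  expect_error(fit_exponential_mean(all_cens, "exclude"),
               class = "smkin_no_events")
})

test_that("the survival MLE handles censoring and dead time", {
  # Right-censored exponential sample: survival MLE stays unbiased.
  withr::with_seed(2, {
    life <- stats::rexp(20000L, 1 / 10)
    cens <- life > 12
    s <- dwell_sample(pmin(life, 12), cens)
  })
  f <- fit_exponential_mean(s, "survival_mle")
  expect_lt(abs(f$mean - 10), 3 * f$sem)
  # Dead time: events below t_min dropped, t_min subtracted.
  withr::with_seed(3, {
    s2 <- dwell_sample(stats::rexp(20000L, 1 / 10))
  })
  f2 <- fit_exponential_mean(s2, t_min = 4)
  expect_lt(abs(f2$mean - 10), 3 * f2$sem)
})

test_that("bleach-rate fits work on lifetimes and decay curves", {
  t_grid <- seq(0, 150, by = 1)
  curve <- list(t_s = t_grid, value = (1 / 30) * exp(-t_grid / 30))
  fit <- fit_bleach_rate(curve)
  expect_equal(fit$tau_bl, 30, tolerance = 1e-8)

  s <- simulate_bleaching_survival(300, 10000L, seed = 4)
  fit2 <- fit_bleach_rate(s)
  expect_lt(abs(fit2$tau_bl - 300), 3 * 300 / sqrt(10000))

  up <- list(t_s = t_grid, value = exp(t_grid / 50))
  expect_error(fit_bleach_rate(up), class = "smkin_fit_failure")
})

test_that("the photobleach correction reproduces the printed receptor off-times", {
  # 5c.c7: tau_obs = (1/5.2 + 1/30)^-1 = 4.432 s with tau_bl = 30 s.
  c1 <- correct_dwell_time(1 / (1 / 5.2 + 1 / 30), 0.05, 30)
  expect_equal(c1$tau_off, 5.2, tolerance = 1e-10)
  # AND: tau_obs = (1/53.8 + 1/300)^-1 = 45.62 s with tau_bl = 300 s.
  c2 <- correct_dwell_time(1 / (1 / 53.8 + 1 / 300), 0.5, 300)
  expect_equal(c2$tau_off, 53.8, tolerance = 1e-10)
  # No-bleaching limit.
  c3 <- correct_dwell_time(4.3, 0.1, Inf)
  expect_equal(c3$tau_off, 4.3)
  expect_error(correct_dwell_time(31, 0.1, 30),
               class = "smkin_undefined_correction")
})

test_that("correction inverts the forward map and is monotone", {
  for (tau_off in c(0.5, 5.2, 53.8, 400)) {
    for (tau_bl in c(30, 300)) {
      tau_obs <- 1 / (1 / tau_off + 1 / tau_bl)
      back <- correct_dwell_time(tau_obs, 0, tau_bl)$tau_off
      expect_equal(back, tau_off, tolerance = 1e-12)
    }
  }
  obs <- seq(1, 25, by = 0.5)
  offs <- vapply(obs, function(o) correct_dwell_time(o, 0, 30)$tau_off,
                 numeric(1))
  expect_true(all(diff(offs) > 0))
})

test_that("the observed dwell pdf is normalized with the printed rate", {
  q <- stats::integrate(dwell_pdf, 0, Inf, tau_off = 5.2, tau_bl = 30)
  expect_lt(abs(q$value - 1), 1e-8)
  expect_equal(dwell_pdf(0, 5.2, 30), 1 / (1 / (1 / 5.2 + 1 / 30)),
               tolerance = 1e-12)
  expect_equal(dwell_pdf(0, 5.2, 30), 0.2256, tolerance = 1e-3)
  expect_equal(dwell_pdf(3, 5.2, Inf), stats::dexp(3, 1 / 5.2))
})

test_that("delta-method and bootstrap uncertainties are consistent", {
  withr::with_seed(5, {
    s <- dwell_sample(stats::rexp(400L, 1 / 4.4))
  })
  delta <- estimate_kinetics(s, tau_bl = 30)
  boot <- estimate_kinetics(s, tau_bl = 30, bootstrap = TRUE, seed = 6)
  expect_equal(boot$tau_off, delta$tau_off)
  expect_lt(abs(boot$tau_off_sem - delta$tau_off_sem),
            0.5 * delta$tau_off_sem)
})

test_that("simulated two-state kinetics recover tau_off across the grid", {
  # simulate -> classify (on positions) -> fit -> correct, over the grid of
  # off-times and bleaching standards; frame interval scaled to each dwell.
  for (cond in list(c(2, 30), c(5.2, 30), c(20, 300), c(53.8, 300))) {
    tau_off <- cond[1]; tau_bl <- cond[2]
    tau_obs <- 1 / (1 / tau_off + 1 / tau_bl)
    dt <- max(0.05, round(tau_obs / 40, 2))
    meta <- acquisition_meta(dt, n_frames = 1200L, field_size = 64L)
    p <- sim_kinetic_params(k_bind = 2 / tau_obs, k_off = 1 / tau_off,
                            k_bl = 1 / tau_bl, v_radial = 0)
    alld <- NULL
    for (seed in 1:2) {
      sim <- simulate_two_state_tracks(p, meta, 10L, seed = 40 + seed)
      fit <- fit_mobility_mixture(step_size_distribution(sim$tracks))
      cl <- classify_bound_segments(sim$tracks, fit, window = 3L)
      alld <- rbind(alld, cl$dwells)
    }
    class(alld) <- c("dwell_sample", "data.frame")
    est <- estimate_kinetics(alld, tau_bl = tau_bl,
                             censor_policy = "survival_mle",
                             t_min = 3 * dt)
    expect_lt(abs(est$tau_off - tau_off), 3 * est$tau_off_sem,
              label = sprintf("tau_off=%g tau_bl=%g: got %.3g +/- %.3g",
                              tau_off, tau_bl, est$tau_off,
                              est$tau_off_sem))
  }
})

test_that("condition comparison combines uncertainties quadratically", {
  withr::with_seed(7, {
    a <- estimate_kinetics(dwell_sample(stats::rexp(500, 1 / 4)), tau_bl = 30)
    b <- estimate_kinetics(dwell_sample(stats::rexp(500, 1 / 2)), tau_bl = 30)
  })
  cmp <- compare_dwell_conditions(a, b)
  expect_equal(cmp$delta_tau_off, a$tau_off - b$tau_off)
  expect_equal(cmp$sem, sqrt(a$tau_off_sem^2 + b$tau_off_sem^2))
})
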