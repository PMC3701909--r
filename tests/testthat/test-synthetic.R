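# Synthetic-data generators: Brownian tracks, two-state kinetics,
# intensity traces, bleaching lifetimes, rendering, bead fields.

test_that("free tracks have the closed-form mean squared step", {
  meta <- meta_short(201L)
  tr <- simulate_free_tracks(0.44, meta, n_tracks = 100L, seed = 1)
  ss <- step_size_distribution(tr)
  expect_length(ss$dr, 100 * 200)
  expected <- 4 * 0.44 * meta$frame_interval          # 0.0308 um^2
  se <- stats::sd(ss$dr^2) / sqrt(length(ss$dr))
  expect_lt(abs(mean(ss$dr^2) - expected), 3 * se)
})

test_that("zero diffusivity gives exactly zero steps", {
  meta <- meta_short(50L)
  tr <- simulate_free_tracks(0, meta, n_tracks = 3L, seed = 2)
  ss <- step_size_distribution(tr)
  expect_true(all(ss$dr == 0))
})

test_that("generators are bit-identical under a repeated seed", {
  meta <- meta_short(30L)
  expect_identical(simulate_free_tracks(0.44, meta, 5L, seed = 3),
                   simulate_free_tracks(0.44, meta, 5L, seed = 3))
  p <- sim_kinetic_params()
  m2 <- meta_long(40L)
  expect_identical(simulate_two_state_tracks(p, m2, 4L, seed = 4),
                   simulate_two_state_tracks(p, m2, 4L, seed = 4))
  expect_identical(simulate_bleaching_survival(30, 100L, seed = 5),
                   simulate_bleaching_survival(30, 100L, seed = 5))
})

test_that("invalid acquisition metadata is rejected", {
  expect_error(acquisition_meta(0), class = "smkin_invalid_metadata")
  expect_error(acquisition_meta(0.1, exposure_time = 0.2),
               class = "smkin_invalid_metadata")
  expect_error(acquisition_meta(0.1, field_size = 8L),
               class = "smkin_invalid_metadata")
})

test_that("visible bound durations follow the competing-exponential mean", {
  # Visible dwell ends by unbinding or bleaching: mean (k_off + k_bl)^-1.
  p <- sim_kinetic_params(k_bind = 0.5, k_off = 1 / 5.2, k_bl = 1 / 30)
  meta <- acquisition_meta(0.5, n_frames = 2000L, field_size = 64L)
  sim <- simulate_two_state_tracks(p, meta, n_tracks = 150L, seed = 6)
  d <- dwells_from_truth(sim$truth)
  dur <- d$duration_s[!d$censored]
  expect_gt(length(dur), 500)
  expected <- 1 / (1 / 5.2 + 1 / 30)                  # 4.43 s
  se <- stats::sd(dur) / sqrt(length(dur))
  expect_lt(abs(mean(dur) - expected), 3 * se)
})

test_that("bound durations pass a Kolmogorov-Smirnov test of exponentiality", {
  # Bound dwells end at rate k_off + k_bl = 0.6/s; each molecule survives
  # ~6 dwells before bleaching, so 1500 molecules give ~9000 events.
  p <- sim_kinetic_params(k_bind = 1, k_off = 0.5, k_bl = 0.1)
  meta <- acquisition_meta(0.5, n_frames = 100L, field_size = 64L)
  dur <- c()
  for (seed in 7:9) {
    sim <- simulate_two_state_tracks(p, meta, n_tracks = 500L, seed = seed)
    iv <- sim$truth$intervals
    complete <- iv$end_cause != "movie_end"
    dur <- c(dur, (iv$end_s - iv$start_s)[complete])
  }
  expect_gt(length(dur), 8000)
  ks <- suppressWarnings(stats::ks.test(dur, "pexp", rate = 0.6))
  expect_gt(ks$p.value, 0.01)
})

test_that("degenerate kinetic regimes label as specified", {
  meta <- meta_long(60L)
  p0 <- sim_kinetic_params(k_bind = 0)
  sim0 <- simulate_two_state_tracks(p0, meta, 5L, seed = 8)
  expect_equal(nrow(sim0$truth$intervals), 0)
  expect_true(all(sim0$truth$states$state == "FREE"))

  pinf <- sim_kinetic_params(k_bind = 5, k_off = 0, k_bl = 0)
  siminf <- simulate_two_state_tracks(pinf, meta, 5L, seed = 9)
  expect_true(all(siminf$truth$intervals$end_cause == "movie_end"))
})

test_that("intensity traces reproduce their segment construction", {
  meta <- acquisition_meta(0.05, n_frames = 10L)
  # Single-molecule level printed for the calibration cell: 47 counts.
  sim <- simulate_intensity_trace(c(47, 0), c(5, 5), noise_sd = 5,
                                  meta = meta, seed = 10)
  seg1 <- sim$trace$counts[sim$truth$segment_of_frame == 1L]
  expect_lt(abs(mean(seg1) - 47), 3 * 5 / sqrt(length(seg1)))

  exact <- simulate_intensity_trace(c(10, 4), c(1, 1), noise_sd = 0,
                                    meta = meta, seed = 11)
  expect_identical(unique(exact$trace$counts), c(10, 4))

  u <- 20
  stair <- simulate_intensity_trace(c(3 * u, 2 * u, u, 0), rep(2, 4),
                                    noise_sd = 0, meta = meta, seed = 12)
  expect_length(stair$truth$change_frames, 3L)

  expect_error(simulate_intensity_trace(numeric(0), numeric(0), 1, meta),
               class = "smkin_invalid_parameter")
})

test_that("bleaching lifetimes have the requested exponential mean", {
  for (tau in c(30, 300)) {
    s <- simulate_bleaching_survival(tau, 10000L, seed = 13 + tau)
    expect_false(any(s$censored))
    expect_lt(abs(mean(s$duration_s) - tau), 3 * tau / sqrt(10000))
  }
  s0 <- simulate_bleaching_survival(30, 50L, t_max = 0, seed = 14)
  expect_true(all(s0$censored))
  expect_true(all(s0$duration_s == 0))
})

test_that("rendered photons are conserved regardless of substeps", {
  meta <- meta_long(2L, field = 48L)
  tr <- stationary_tracks(cbind(2.5, 2.5), meta)
  sums <- vapply(c(1L, 5L, 25L), function(ss) {
    st <- render_frames(tr, psf_sigma = 0.125, photons_per_frame = 600,
                        substeps = ss, noise = camera_noise(0, 0), seed = 15)
    sum(st[, , 1])
  }, numeric(1))
  expect_true(all(abs(sums - 600) < 0.5))
})

test_that("long-exposure motion blur lowers the peak of a fast diffuser", {
  meta <- acquisition_meta(0.5, exposure_time = 0.5, field_size = 48L,
                           n_frames = 2L)
  moving <- track_set(data.frame(track_id = 1L, frame = 0:1,
                                 t_s = c(0, 0.5),
                                 x_um = c(1.5, 2.44), y_um = 2.5), meta)
  still <- stationary_tracks(cbind(1.5, 2.5), meta)
  st_m <- render_frames(moving, psf_sigma = 0.125, photons_per_frame = 600,
                        substeps = 29L, noise = camera_noise(0, 0),
                        bridge_d = 0.44, seed = 16)
  st_s <- render_frames(still, psf_sigma = 0.125, photons_per_frame = 600,
                        substeps = 29L, noise = camera_noise(0, 0), seed = 16)
  expect_lt(max(st_m[, , 1]), 0.5 * max(st_s[, , 1]))
})

test_that("an empty field renders to the camera offset", {
  meta <- acquisition_meta(0.5, field_size = 32L, n_frames = 3L)
  empty <- track_set(data.frame(track_id = integer(0), frame = integer(0),
                                t_s = numeric(0), x_um = numeric(0),
                                y_um = numeric(0)), meta)
  st <- render_frames(empty, noise = camera_noise(offset = 100, read_sd = 0),
                      seed = 17)
  expect_equal(mean(st), 100)
})

test_that("bead fields honor the generating transform", {
  id <- identity_channel_map(1L)
  bf <- simulate_bead_field(20L, id, loc_noise = 0, seed = 18)
  expect_equal(bf$src, bf$dst, ignore_attr = TRUE)
  expect_error(simulate_bead_field(3L, identity_channel_map(2L), seed = 19),
               class = "smkin_underdetermined")
})

test_that("frame stacks survive a 16-bit TIFF round trip", {
  meta <- acquisition_meta(0.5, field_size = 32L, n_frames = 4L)
  tr <- stationary_tracks(cbind(1.6, 1.6), meta)
  st <- render_frames(tr, photons_per_frame = 500,
                      noise = camera_noise(100, 2), seed = 20)
  path <- tempfile(fileext = ".tif")
  write_frame_stack(st, path)
  back <- read_frame_stack(path, meta)
  expect_equal(dim(back), dim(st))
  expect_lt(max(abs(back - round(st))), 0.51)
})
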