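# Recruitment stoichiometry: window integration, single-molecule
# calibration, molecule counting.

render_feature_stack <- function(m_emitters, meta, photons = 100,
                                 at = NULL, seed = 1, read_sd = 1) {
  ext <- meta$field_size * meta$pixel_size
  if (is.null(at)) at <- ext / 2
  rows <- lapply(seq_len(m_emitters), function(j) {
    data.frame(track_id = j, frame = 0:(meta$n_frames - 1L),
               t_s = (0:(meta$n_frames - 1L)) * meta$frame_interval,
               x_um = at[1], y_um = at[2], state = "BOUND")
  })
  tr <- track_set(do.call(rbind, rows), meta)
  render_frames(tr, psf_sigma = 0.8 * meta$pixel_size,
                photons_per_frame = photons, substeps = 1L,
                noise = camera_noise(100, read_sd), seed = seed)
}

anchor_at <- function(xy, meta) {
  track_set(data.frame(track_id = 1L, frame = 0:(meta$n_frames - 1L),
                       t_s = (0:(meta$n_frames - 1L)) * meta$frame_interval,
                       x_um = xy[1], y_um = xy[2]), meta)
}

test_that("the 3x3 window captures the expected PSF fraction, uniformly", {
  meta <- acquisition_meta(0.5, field_size = 32L, n_frames = 10L)
  # expected capture of a pixel-integrated Gaussian, sigma = 0.8 px,
  # centered on a pixel: (2*pnorm(1.5/0.8) - 1)^2 ~ 0.94; off-center less.
  fracs <- c()
  for (pos in list(c(10, 10), c(10.35, 15.6), c(21.7, 9.2))) {
    xy <- pos * 0.105
    st <- render_feature_stack(1L, meta, photons = 200, at = xy,
                               seed = 40, read_sd = 0.5)
    tra <- integrate_local_intensity(st, anchor_at(xy, meta))[[1]]
    fracs <- c(fracs, mean(tra$counts) / 200)
  }
  expect_true(all(fracs > 0.80 & fracs < 1.0))
  expect_lt(max(fracs) - min(fracs), 0.12)
  # constant across frames within noise
  xy <- c(10, 10) * 0.105
  st <- render_feature_stack(1L, meta, photons = 200, at = xy, seed = 41)
  tra <- integrate_local_intensity(st, anchor_at(xy, meta))[[1]]
  expect_lt(stats::sd(tra$counts), 10)
})

test_that("background-only stacks integrate to about zero", {
  meta <- acquisition_meta(0.5, field_size = 32L, n_frames = 20L)
  arr <- array(100 + stats::rnorm(32 * 32 * 20, 0, 2), c(32, 32, 20))
  st <- structure(arr, meta = meta, class = "frame_stack")
  tra <- integrate_local_intensity(st, anchor_at(c(1.6, 1.6), meta))[[1]]
  expect_lt(abs(mean(tra$counts)), 3)
})

test_that("anchor gaps yield missing values and edge anchors are partial", {
  meta <- acquisition_meta(0.5, field_size = 32L, n_frames = 10L)
  st <- render_feature_stack(1L, meta, seed = 42)
  gap_anchor <- track_set(
    data.frame(track_id = 1L, frame = c(0:3, 6:9),
               t_s = c(0:3, 6:9) * 0.5,
               x_um = 16 * 0.105, y_um = 16 * 0.105), meta)
  tra <- integrate_local_intensity(st, gap_anchor)[[1]]
  expect_true(all(is.na(tra$counts[tra$t_s %in% c(2, 2.5)])))
  edge <- integrate_local_intensity(st, anchor_at(c(0.05, 0.05), meta))[[1]]
  expect_true(attr(edge, "partial"))
})

test_that("single-molecule calibration recovers the unit and rejects dimers", {
  m <- acquisition_meta(0.05, n_frames = 16L)
  traces <- list(); cps <- list()
  for (i in 1:6) {
    sim <- simulate_intensity_trace(c(47, 0), c(4 + 0.2 * i, 4),
                                    noise_sd = 2, meta = m, seed = 50 + i)
    traces[[i]] <- sim$trace
  }
  cal <- calibrate_single_molecule_intensity(traces)
  expect_equal(cal$n, 6L)
  expect_lt(abs(cal$unit - 47), 3 * cal$sem + 0.5)

  dimer <- simulate_intensity_trace(c(94, 47, 0), c(3, 3, 3), noise_sd = 2,
                                    meta = m, seed = 60)
  cal2 <- calibrate_single_molecule_intensity(c(traces, list(dimer$trace)))
  expect_equal(cal2$n, 6L)
  expect_equal(cal2$rejected, 7L)

  expect_error(calibrate_single_molecule_intensity(list()),
               class = "smkin_no_events")
})

test_that("the worked stoichiometry numbers come out exactly", {
  s <- estimate_stoichiometry(136.0, 47, labeled_fraction = 0.5,
                              feature_sem = 0.04)
  expect_equal(s$n_visible_2sf, 2.9)
  expect_equal(round(s$n_total), 6)
  expect_error(estimate_stoichiometry(100, 0),
               class = "smkin_invalid_parameter")
})

test_that("counting is linear in the number of coincident unit emitters", {
  meta <- acquisition_meta(0.5, field_size = 32L, n_frames = 12L)
  xy <- c(16, 16) * 0.105
  unit_st <- render_feature_stack(1L, meta, photons = 100, at = xy, seed = 70)
  unit <- mean(integrate_local_intensity(unit_st,
                                         anchor_at(xy, meta))[[1]]$counts)
  for (m_true in c(2L, 3L, 5L, 10L)) {
    st <- render_feature_stack(m_true, meta, photons = 100, at = xy,
                               seed = 70 + m_true)
    feat <- mean(integrate_local_intensity(st, anchor_at(xy, meta))[[1]]$counts)
    est <- estimate_stoichiometry(feat, unit, labeled_fraction = 1)
    expect_lt(abs(est$n_visible - m_true), 0.15 * m_true)
  }
})

test_that("stoichiometry is invariant to a global gain change", {
  a <- estimate_stoichiometry(136.0, 47)
  b <- estimate_stoichiometry(136.0 * 3.7, 47 * 3.7)
  expect_equal(a$n_visible, b$n_visible)
  expect_equal(a$n_total, b$n_total)
})

test_that("a window that is not an odd pixel span is rejected", {
  meta <- acquisition_meta(0.5, field_size = 32L, n_frames = 4L)
  st <- render_feature_stack(1L, meta, seed = 80)
  expect_error(integrate_local_intensity(st, anchor_at(c(1.6, 1.6), meta),
                                         window_um = 0.2),
               class = "smkin_invalid_parameter")
})
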