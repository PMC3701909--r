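# Spot detection and track linking.

test_that("a single rendered emitter is localized within 0.1 px", {
  meta <- acquisition_meta(0.5, field_size = 32L, n_frames = 1L)
  tr <- stationary_tracks(cbind(1.60, 1.23), meta)
  st <- render_frames(tr, psf_sigma = 0.125, photons_per_frame = 600,
                      noise = camera_noise(100, 0), seed = 1)
  d <- detect_spots(st[, , 1], intensity_min = 50)
  expect_equal(nrow(d), 1L)
  expect_lt(abs(d$x_px - 1.60 / 0.105), 0.1)
  expect_lt(abs(d$y_px - 1.23 / 0.105), 0.1)
})

test_that("two separated emitters give two accurate localizations", {
  meta <- acquisition_meta(0.5, field_size = 48L, n_frames = 1L)
  xy <- rbind(c(1.60, 1.23), c(1.60 + 10 * 0.105, 1.23 + 10 * 0.105))
  tr <- stationary_tracks(xy, meta)
  st <- render_frames(tr, psf_sigma = 0.125, photons_per_frame = 600,
                      noise = camera_noise(100, 2), seed = 2)
  d <- detect_spots(st[, , 1], intensity_min = 50)
  expect_equal(nrow(d), 2L)
  d <- d[order(d$x_px), ]
  for (i in 1:2) {
    expect_lt(abs(d$x_px[i] - xy[i, 1] / 0.105), 0.2)
    expect_lt(abs(d$y_px[i] - xy[i, 2] / 0.105), 0.2)
  }
})

test_that("noise-only frames yield no localizations", {
  set.seed(3)
  blank <- matrix(100 + stats::rnorm(48 * 48, 0, 2), 48, 48)
  expect_equal(nrow(detect_spots(blank, intensity_min = 50)), 0L)
})

test_that("saturated frames warn but still process", {
  frame <- matrix(100, 32, 32)
  frame[16, 16] <- 70000
  expect_warning(detect_spots(frame, intensity_min = 50),
                 class = "smkin_saturated")
})

test_that("the assignment solver matches brute-force enumeration", {
  withr::with_seed(4, {
    for (rep in 1:20) {
      n <- sample(2:6, 1)
      cost <- matrix(stats::runif(n * n), n, n)
      got <- solve_assignment(cost)
      ref <- brute_assignment(cost)
      expect_equal(sum(cost[cbind(seq_len(n), got)]), ref$cost,
                   tolerance = 1e-12)
    }
  })
})

test_that("one persistent molecule links into a single full-length track", {
  meta <- meta_long(50L)
  locs <- data.frame(frame = 0:49, x_um = 2 + 0.01 * (0:49), y_um = 3)
  ts <- link_tracks(locs, meta, max_disp = 0.5)
  expect_equal(length(unique(ts$track_id)), 1L)
  expect_equal(nrow(ts), 50L)
})

test_that("well-separated molecules never swap identity", {
  meta <- meta_long(60L)
  swaps <- 0L
  for (seed in 1:100) {
    withr::with_seed(seed, {
      # Two diffusing molecules kept > max_disp apart by construction.
      x1 <- 1 + cumsum(stats::rnorm(60, 0, 0.05))
      x2 <- 5 + cumsum(stats::rnorm(60, 0, 0.05))
      locs <- data.frame(frame = rep(0:59, 2), x_um = c(x1, x2),
                         y_um = rep(c(1, 5), each = 60),
                         mol = rep(1:2, each = 60))
    })
    ts <- link_tracks(locs, meta, max_disp = 0.5)
    tab <- table(ts$track_id, ts$mol)
    if (!all(rowSums(tab > 0) == 1L)) swaps <- swaps + 1L
  }
  expect_equal(swaps, 0L)
})

test_that("gap closing bridges a single missed detection", {
  meta <- meta_long(10L)
  locs <- data.frame(frame = c(0, 1, 3, 4), x_um = 1, y_um = 1)
  with_gap <- link_tracks(locs, meta, max_disp = 0.5, max_gap = 1L)
  expect_equal(length(unique(with_gap$track_id)), 1L)
  without <- link_tracks(locs, meta, max_disp = 0.5, max_gap = 0L)
  expect_equal(length(unique(without$track_id)), 2L)
})

test_that("render-detect-link round trip recovers slow tracks nearly fully", {
  # High-SNR, well-separated slow molecules: >= 99% of samples recovered,
  # no spurious track persisting more than 3 frames.
  meta <- acquisition_meta(0.5, field_size = 64L, n_frames = 40L)
  xy <- rbind(c(1.5, 1.5), c(4.8, 1.6), c(1.6, 4.9), c(5.0, 5.0))
  p <- sim_kinetic_params(d_free = 0.44, d_bound = 0.005, v_radial = 0,
                          k_bind = 0, k_off = 1, k_bl = 0)
  rows <- lapply(seq_len(nrow(xy)), function(i) {
    withr::with_seed(100 + i, {
      data.frame(track_id = i, frame = 0:39, t_s = (0:39) * 0.5,
                 x_um = xy[i, 1] + cumsum(stats::rnorm(40, 0, 0.05)),
                 y_um = xy[i, 2] + cumsum(stats::rnorm(40, 0, 0.05)),
                 state = "BOUND")
    })
  })
  truth <- track_set(do.call(rbind, rows), meta)
  st <- render_frames(truth, psf_sigma = 0.125, photons_per_frame = 600,
                      noise = camera_noise(100, 2), seed = 5)
  locs <- detect_spots_stack(st, intensity_min = 60)
  ts <- link_tracks(locs, meta, max_disp = 0.5, max_gap = 1L)
  # recovery rate
  tp <- as.data.frame(truth)
  by_frame <- split(as.data.frame(ts), ts$frame)
  hit <- vapply(seq_len(nrow(tp)), function(i) {
    cand <- by_frame[[as.character(tp$frame[i])]]
    !is.null(cand) && min(sqrt((cand$x_um - tp$x_um[i])^2 +
                               (cand$y_um - tp$y_um[i])^2)) < 0.2
  }, logical(1))
  expect_gte(mean(hit), 0.99)
  # no long spurious tracks
  lens <- table(ts$track_id)
  real_ids <- unique(unlist(lapply(seq_len(nrow(tp)), function(i) {
    cand <- by_frame[[as.character(tp$frame[i])]]
    d <- sqrt((cand$x_um - tp$x_um[i])^2 + (cand$y_um - tp$y_um[i])^2)
    cand$track_id[d < 0.2]
  })))
  spurious <- lens[!names(lens) %in% as.character(real_ids)]
  expect_true(all(spurious <= 3))
})
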