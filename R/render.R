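#' Camera noise specification
#'
#' @param offset Constant camera offset, counts.
#' @param read_sd Gaussian read-noise SD, counts.
#' @param shot If `TRUE`, photon signal is Poisson-distributed (shot
#'   noise); otherwise the expected photon count is deposited directly.
#' @return A `camera_noise` list.
#' @export
camera_noise <- function(offset = 100, read_sd = 2, shot = FALSE) {
  if (offset < 0 || read_sd < 0) {
    stop_smkin("offset and read_sd must be >= 0", "smkin_invalid_parameter")
  }
  structure(list(offset = offset, read_sd = read_sd, shot = isTRUE(shot)),
            class = "camera_noise")
}

#' Render synthetic camera frames from tracks
#'
#' Deposits each visible emitter as a pixel-integrated 2D Gaussian point
#' spread function at `substeps` intra-exposure positions, so that fast
#' diffusers imaged with long exposures smear over several pixels and sink
#' into background while slow, bound molecules stay diffraction-limited —
#' the "hardware filtering" that isolates receptor-bound ligands. The
#' intra-exposure path interpolates between consecutive frame positions
#' (a Brownian bridge when `bridge_d` is given, the straight chord
#' otherwise). Total deposited photons per emitter per frame equal
#' `photons_per_frame` regardless of `substeps`.
#'
#' @param tracks A [track_set()]; rows with `state == "BLEACHED"` deposit
#'   nothing.
#' @param psf_sigma PSF standard deviation, micrometers.
#' @param photons_per_frame Expected photons per emitter per frame, counts.
#' @param substeps Intra-exposure positions per frame (>= 1, default 25).
#' @param noise A [camera_noise()] specification.
#' @param bridge_d Diffusivity used for the Brownian-bridge fluctuation of
#'   the intra-exposure path, um^2/s. Either a single number applied to all
#'   emitters, or a named vector keyed by the track `state` column (e.g.
#'   `c(FREE = 0.44, BOUND = 0.005)`) so each mobility state blurs with its
#'   own diffusivity; `NULL` (default) uses deterministic chord
#'   interpolation.
#' @param seed Integer seed.
#' @return Object of class `frame_stack`: numeric array
#'   `[y_px, x_px, frame]` in counts, with attributes `meta` and `noise`.
#' @export
render_frames <- function(tracks, psf_sigma = 0.125,
                          photons_per_frame = 400, substeps = 25L,
                          noise = camera_noise(), bridge_d = NULL,
                          seed = NULL) {
  stopifnot(inherits(tracks, "track_set"))
  meta <- track_meta(tracks)
  if (psf_sigma <= 0) {
    stop_smkin("psf_sigma must be positive", "smkin_invalid_parameter")
  }
  if (!is_count(substeps)) {
    stop_smkin("substeps must be a positive integer", "smkin_invalid_parameter")
  }
  if (!inherits(noise, "camera_noise")) noise <- do.call(camera_noise, noise)
  px <- meta$pixel_size
  nx <- meta$field_size[1]; ny <- meta$field_size[2]
  nf <- meta$n_frames
  ext <- field_extent_um(meta)
  frac <- meta$exposure_time / meta$frame_interval

  out_of_field <- any(tracks$x_um < -0.5 * px | tracks$x_um > ext[1] - 0.5 * px |
                      tracks$y_um < -0.5 * px | tracks$y_um > ext[2] - 0.5 * px)
  if (out_of_field) {
    warn_smkin("some track positions fall outside the field; emission clipped",
               "smkin_clipped_emitters")
  }

  df <- as.data.frame(tracks)
  if (!is.null(df$state)) df <- df[df$state != "BLEACHED", , drop = FALSE]
  by_track <- split(df, df$track_id)

  with_seed(seed, {
    stack <- array(0, dim = c(ny, nx, nf))
    for (tr in by_track) {
      o <- order(tr$frame)
      fr <- tr$frame[o]; xs <- tr$x_um[o]; ys <- tr$y_um[o]
      st_lab <- if (is.null(tr$state)) rep(NA_character_, length(fr))
                else tr$state[o]
      nxt <- match(fr + 1L, fr)
      for (i in seq_along(fr)) {
        f <- fr[i] + 1L
        x0 <- xs[i]; y0 <- ys[i]
        if (is.na(nxt[i])) {
          x1 <- x0; y1 <- y0
        } else {
          x1 <- xs[nxt[i]]; y1 <- ys[nxt[i]]
        }
        d_i <- bridge_d
        if (!is.null(bridge_d) && !is.null(names(bridge_d))) {
          d_i <- if (!is.na(st_lab[i]) && st_lab[i] %in% names(bridge_d))
            unname(bridge_d[[st_lab[i]]]) else 0
        }
        pos <- intra_exposure_path(x0, y0, x1, y1, substeps, frac,
                                   meta$frame_interval, d_i)
        w <- photons_per_frame / substeps
        for (j in seq_len(substeps)) {
          p <- psf_patch(pos[j, 1L], pos[j, 2L], psf_sigma, px, nx, ny)
          if (is.null(p)) next
          stack[p$yi + 1L, p$xi + 1L, f] <-
            stack[p$yi + 1L, p$xi + 1L, f] + w * p$patch
        }
      }
    }
    if (noise$shot) {
      stack[] <- stats::rpois(length(stack), lambda = pmax(stack, 0))
    }
    stack <- stack + noise$offset
    if (noise$read_sd > 0) {
      stack <- stack + array(stats::rnorm(length(stack), 0, noise$read_sd),
                             dim = dim(stack))
    }
    stack[stack < 0] <- 0
    structure(stack, meta = meta, noise = noise, class = "frame_stack")
  })
}

# Positions of an emitter at substep midpoints of the exposure window.
# Chord interpolation between frame positions; with bridge_d set, a
# sequentially sampled Brownian bridge pinned at both frame positions.
intra_exposure_path <- function(x0, y0, x1, y1, substeps, frac,
                                frame_interval, bridge_d) {
  s <- (seq_len(substeps) - 0.5) / substeps * frac  # fraction of interval
  if (is.null(bridge_d) || bridge_d <= 0) {
    return(cbind(x0 + s * (x1 - x0), y0 + s * (y1 - y0)))
  }
  t_abs <- s * frame_interval
  out <- matrix(NA_real_, substeps, 2L)
  cur <- c(x0, y0); t_cur <- 0
  for (j in seq_len(substeps)) {
    dt <- t_abs[j] - t_cur
    rem <- frame_interval - t_cur
    mu <- cur + (c(x1, y1) - cur) * dt / rem
    v <- 2 * bridge_d * dt * (rem - dt) / rem
    cur <- mu + stats::rnorm(2L, 0, sqrt(max(v, 0)))
    t_cur <- t_abs[j]
    out[j, ] <- cur
  }
  out
}

# Pixel-integrated Gaussian PSF patch, truncated at +/- 4 sigma.
# Returns NULL when fully off-field, else list(xi, yi, patch) with 0-based
# pixel index vectors and the photon-fraction matrix.
psf_patch <- function(x_um, y_um, sigma, px, nx, ny) {
  half <- 4 * sigma
  ix0 <- max(0L, as.integer(floor((x_um - half) / px)))
  ix1 <- min(nx - 1L, as.integer(ceiling((x_um + half) / px)))
  iy0 <- max(0L, as.integer(floor((y_um - half) / px)))
  iy1 <- min(ny - 1L, as.integer(ceiling((y_um + half) / px)))
  if (ix0 > ix1 || iy0 > iy1) return(NULL)
  xi <- ix0:ix1; yi <- iy0:iy1
  fx <- stats::pnorm(((xi + 0.5) * px - x_um) / sigma) -
        stats::pnorm(((xi - 0.5) * px - x_um) / sigma)
  fy <- stats::pnorm(((yi + 0.5) * px - y_um) / sigma) -
        stats::pnorm(((yi - 0.5) * px - y_um) / sigma)
  list(xi = xi, yi = yi, patch = outer(fy, fx))
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<frame_stack> %d frames of %dx%d px, counts in [%.4g, %.4g]\n",
              d[3], d[2], d[1], min(x), max(x)))
  invisible(x)
}

#' Write a frame stack as a multi-page 16-bit TIFF
#'
#' Counts are rounded, clamped to `[0, 65535]` and written one page per
#' frame.
#'
#' @param stack A `frame_stack` (or numeric array `[y, x, frame]`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_frame_stack <- function(stack, path) {
  nf <- dim(stack)[3]
  pages <- lapply(seq_len(nf), function(f) {
    m <- round(stack[, , f])
    m[m < 0] <- 0; m[m > 65535] <- 65535
    m / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page 16-bit TIFF as a frame stack
#'
#' @param path TIFF file path.
#' @param meta Optional [acquisition_meta()] to attach.
#' @return Numeric array `[y, x, frame]` in counts (class `frame_stack`
#'   when `meta` is supplied).
#' @export
read_frame_stack <- function(path, meta = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]), length(pages)))
  for (f in seq_along(pages)) arr[, , f] <- pages[[f]] * 65535
  if (!is.null(meta)) {
    arr <- structure(arr, meta = meta, class = "frame_stack")
  }
  arr
}
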