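#' Construct a track set
#'
#' A `track_set` is the package's unit container for single-particle
#' trajectories: a data frame with columns `track_id`, `frame` (0-based),
#' `t_s`, `x_um`, `y_um` and optionally `state` (`FREE`, `BOUND`, `BLEACHED`
#' or `UNKNOWN`), carrying the acquisition metadata as an attribute.
#'
#' @param df Data frame with at least `track_id`, `frame`, `t_s`, `x_um`,
#'   `y_um`.
#' @param meta An [acquisition_meta()] object.
#' @return The data frame with class `track_set` and attribute `meta`.
#' @export
track_set <- function(df, meta) {
  stopifnot(inherits(meta, "acquisition_meta"))
  need <- c("track_id", "frame", "t_s", "x_um", "y_um")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop_smkin(paste0("track_set missing columns: ",
                      paste(miss, collapse = ", ")), "smkin_schema")
  }
  ok <- tapply(df$frame, df$track_id, function(f) all(diff(f) > 0))
  if (length(ok) && !all(unlist(ok))) {
    stop_smkin("frames must be strictly increasing within each track",
               "smkin_schema")
  }
  structure(as.data.frame(df), meta = meta,
            class = c("track_set", "data.frame"))
}

#' @export
print.track_set <- function(x, ...) {
  cat(sprintf("<track_set> %d tracks, %d samples\n",
              length(unique(x$track_id)), nrow(x)))
  NextMethod()
}

track_meta <- function(tracks) attr(tracks, "meta", exact = TRUE)

#' Simulate freely diffusing membrane-tethered molecules
#'
#' Generates pure 2D Brownian trajectories, the mobility observed for
#' bilayer-tethered peptide-MHC away from cell contacts. Each per-frame
#' increment is Gaussian per axis with variance `2 * d_coeff * frame_interval`,
#' so displacement magnitudes are Rayleigh with RMS `sqrt(4 * D * dt)`.
#' Starting positions are uniform over the field of view; trajectories are
#' not confined (they may leave the field).
#'
#' @param d_coeff Lateral diffusion coefficient, um^2/s (>= 0).
#' @param meta [acquisition_meta()].
#' @param n_tracks Number of independent molecules.
#' @param seed Integer seed; the same seed reproduces the output exactly.
#' @return A [track_set()] with `state = "FREE"` throughout.
#' @examples
#' meta <- acquisition_meta(frame_interval = 0.0175, n_frames = 50)
#' tr <- simulate_free_tracks(0.44, meta, n_tracks = 5, seed = 1)
#' head(tr)
#' @export
simulate_free_tracks <- function(d_coeff, meta, n_tracks, seed = NULL) {
  stopifnot(inherits(meta, "acquisition_meta"))
  if (!is.numeric(d_coeff) || d_coeff < 0) {
    stop_smkin("d_coeff must be >= 0", "smkin_invalid_parameter")
  }
  if (!is_count(n_tracks)) {
    stop_smkin("n_tracks must be a positive integer", "smkin_invalid_parameter")
  }
  nf <- meta$n_frames
  ext <- field_extent_um(meta)
  sd_step <- sqrt(2 * d_coeff * meta$frame_interval)
  with_seed(seed, {
    x0 <- stats::runif(n_tracks, 0, ext[1])
    y0 <- stats::runif(n_tracks, 0, ext[2])
    dx <- matrix(stats::rnorm((nf - 1L) * n_tracks, 0, sd_step),
                 nrow = nf - 1L)
    dy <- matrix(stats::rnorm((nf - 1L) * n_tracks, 0, sd_step),
                 nrow = nf - 1L)
    x <- rbind(x0, sweep(apply(dx, 2, cumsum), 2L, x0, `+`))
    y <- rbind(y0, sweep(apply(dy, 2, cumsum), 2L, y0, `+`))
    if (nf == 1L) { x <- matrix(x0, 1L); y <- matrix(y0, 1L) }
    df <- data.frame(
      track_id = rep(seq_len(n_tracks), each = nf),
      frame = rep(0:(nf - 1L), n_tracks),
      t_s = rep(0:(nf - 1L), n_tracks) * meta$frame_interval,
      x_um = as.vector(x),
      y_um = as.vector(y),
      state = "FREE")
    track_set(df, meta)
  })
}

#' Kinetic parameters for the two-state binding simulation
#'
#' The kinetic scheme is a memoryless three-state chain: a freely diffusing
#' ligand binds a receptor at rate `k_bind`, the bound complex unbinds at
#' rate `k_off` (mean dwell `1/k_off`) or photobleaches at rate `k_bl`
#' (mean `1/k_bl`); bleaching ends the molecule's visibility. Bound
#' complexes retain a small residual diffusivity `d_bound` and drift at
#' speed `v_radial` toward a focal point, emulating centripetal transport
#' of ligand-receptor complexes in the cell contact.
#'
#' @param d_free Free-state diffusion coefficient, um^2/s.
#' @param d_bound Bound-state residual diffusion, um^2/s (< `d_free`).
#' @param v_radial Bound-state directed speed toward the center, um/s.
#' @param k_bind Free -> bound rate, 1/s.
#' @param k_off Bound -> free rate, 1/s.
#' @param k_bl Bound -> bleached rate, 1/s.
#' @param bleach_free If `TRUE`, free molecules also bleach at `k_bl`
#'   (default `FALSE`: only the bound, slow-moving standard bleaches).
#' @return A `sim_kinetic_params` list.
#' @export
sim_kinetic_params <- function(d_free = 0.44, d_bound = 0.005,
                               v_radial = 0.05, k_bind = 0.1,
                               k_off = 1 / 5.2, k_bl = 1 / 30,
                               bleach_free = FALSE) {
  vals <- c(d_free = d_free, d_bound = d_bound, v_radial = v_radial,
            k_bind = k_bind, k_off = k_off, k_bl = k_bl)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop_smkin("all kinetic parameters must be finite and >= 0",
               "smkin_invalid_parameter")
  }
  if (d_free <= d_bound) {
    stop_smkin("d_free must exceed d_bound", "smkin_invalid_parameter")
  }
  structure(list(d_free = d_free, d_bound = d_bound, v_radial = v_radial,
                 k_bind = k_bind, k_off = k_off, k_bl = k_bl,
                 bleach_free = isTRUE(bleach_free)),
            class = "sim_kinetic_params")
}

# Continuous-time state path of one molecule over [0, t_end].
# Returns data.frame(start, end, state, end_cause) where end_cause is one of
# bind, unbind, bleach, movie_end.
sim_state_path <- function(params, t_end) {
  starts <- ends <- numeric(0)
  states <- causes <- character(0)
  t <- 0; state <- "FREE"
  repeat {
    if (state == "FREE") {
      r_bind <- params$k_bind
      r_bl <- if (params$bleach_free) params$k_bl else 0
      rate <- r_bind + r_bl
      dt <- if (rate > 0) stats::rexp(1L, rate) else Inf
      if (t + dt >= t_end) {
        starts <- c(starts, t); ends <- c(ends, t_end)
        states <- c(states, "FREE"); causes <- c(causes, "movie_end")
        break
      }
      cause <- if (stats::runif(1L) < r_bind / rate) "bind" else "bleach"
      starts <- c(starts, t); ends <- c(ends, t + dt)
      states <- c(states, "FREE"); causes <- c(causes, cause)
      t <- t + dt
      if (cause == "bleach") break
      state <- "BOUND"
    } else {
      rate <- params$k_off + params$k_bl
      dt <- if (rate > 0) stats::rexp(1L, rate) else Inf
      if (t + dt >= t_end) {
        starts <- c(starts, t); ends <- c(ends, t_end)
        states <- c(states, "BOUND"); causes <- c(causes, "movie_end")
        break
      }
      cause <- if (stats::runif(1L) < params$k_off / rate) "unbind" else "bleach"
      starts <- c(starts, t); ends <- c(ends, t + dt)
      states <- c(states, "BOUND"); causes <- c(causes, cause)
      t <- t + dt
      if (cause == "bleach") break
      state <- "FREE"
    }
  }
  data.frame(start = starts, end = ends, state = states, end_cause = causes)
}

reflect_into <- function(x, lo, hi) {
  # Reflecting boundary: fold coordinates back into [lo, hi].
  w <- hi - lo
  y <- (x - lo) %% (2 * w)
  lo + ifelse(y > w, 2 * w - y, y)
}

#' Simulate two-state (free/bound) trajectories with photobleaching
#'
#' Molecules alternate between free diffusion (`d_free`) and a bound state
#' (`d_bound` plus drift of speed `v_radial` toward `center`) with
#' exponential waiting times at rates `k_bind` and `k_off`; while bound
#' they photobleach at rate `k_bl`, which terminates the track. The
#' returned ground truth is the oracle for every downstream stage: it holds
#' the per-frame state label of each molecule and every bound interval with
#' its end cause (`unbind`, `bleach` or `movie_end`).
#'
#' @param params [sim_kinetic_params()].
#' @param meta [acquisition_meta()].
#' @param n_tracks Number of molecules.
#' @param center Focal point of bound-state transport, um; default field
#'   center.
#' @param boundary `"none"` (free Brownian motion, may leave the field) or
#'   `"reflect"` (reflecting walls at the field edges, for rendering long
#'   movies).
#' @param seed Integer seed.
#' @return A list with elements `tracks` (a [track_set()]; rows stop at
#'   bleaching) and `truth` (class `ground_truth`: `$states` per-frame
#'   labels, `$intervals` bound intervals with end causes).
#' @examples
#' meta <- acquisition_meta(frame_interval = 0.5, n_frames = 60)
#' sim <- simulate_two_state_tracks(sim_kinetic_params(), meta,
#'                                  n_tracks = 3, seed = 1)
#' table(sim$truth$states$state)
#' @export
simulate_two_state_tracks <- function(params, meta, n_tracks,
                                      center = NULL,
                                      boundary = c("none", "reflect"),
                                      seed = NULL) {
  stopifnot(inherits(params, "sim_kinetic_params"),
            inherits(meta, "acquisition_meta"))
  if (!is_count(n_tracks)) {
    stop_smkin("n_tracks must be a positive integer", "smkin_invalid_parameter")
  }
  boundary <- match.arg(boundary)
  ext <- field_extent_um(meta)
  if (is.null(center)) center <- ext / 2
  if (any(center < 0) || any(center > ext)) {
    stop_smkin("center must lie inside the field", "smkin_invalid_parameter")
  }
  nf <- meta$n_frames
  t_end <- nf * meta$frame_interval
  frame_t <- (0:(nf - 1L)) * meta$frame_interval

  with_seed(seed, {
    track_rows <- vector("list", n_tracks)
    state_rows <- vector("list", n_tracks)
    int_rows <- vector("list", n_tracks)
    for (id in seq_len(n_tracks)) {
      path <- sim_state_path(params, t_end)
      bleach_t <- if (any(path$end_cause == "bleach")) max(path$end) else Inf

      # Per-frame state at the frame sampling time.
      idx <- findInterval(frame_t, path$start)
      lab <- path$state[idx]
      lab[frame_t >= bleach_t] <- "BLEACHED"
      visible <- frame_t < bleach_t

      # Position path over the merged grid of frame times and state changes.
      grid <- sort(unique(c(frame_t, path$start, path$end)))
      grid <- grid[grid <= t_end]
      pos <- matrix(NA_real_, length(grid), 2L)
      pos[1L, ] <- stats::runif(2L, 0, ext)
      for (j in seq_len(length(grid) - 1L)) {
        dt <- grid[j + 1L] - grid[j]
        st <- path$state[findInterval(grid[j], path$start)]
        d <- if (st == "BOUND") params$d_bound else params$d_free
        step <- stats::rnorm(2L, 0, sqrt(2 * d * dt))
        p <- pos[j, ] + step
        if (st == "BOUND" && params$v_radial > 0) {
          to_c <- center - pos[j, ]
          dist <- sqrt(sum(to_c^2))
          if (dist > 0) {
            adv <- min(params$v_radial * dt, dist)
            p <- p + to_c / dist * adv
          }
        }
        if (boundary == "reflect") {
          p[1] <- reflect_into(p[1], 0, ext[1])
          p[2] <- reflect_into(p[2], 0, ext[2])
        }
        pos[j + 1L, ] <- p
      }
      at <- match(frame_t, grid)
      keep <- which(visible)
      track_rows[[id]] <- data.frame(
        track_id = id, frame = keep - 1L, t_s = frame_t[keep],
        x_um = pos[at[keep], 1L], y_um = pos[at[keep], 2L],
        state = lab[keep])
      state_rows[[id]] <- data.frame(
        track_id = id, frame = 0:(nf - 1L), state = lab)
      b <- path[path$state == "BOUND", , drop = FALSE]
      if (nrow(b)) {
        int_rows[[id]] <- data.frame(
          track_id = id, start_s = b$start, end_s = b$end,
          end_cause = b$end_cause)
      }
    }
    tracks <- track_set(do.call(rbind, track_rows), meta)
    truth <- structure(
      list(states = do.call(rbind, state_rows),
           intervals = if (length(ii <- Filter(Negate(is.null), int_rows)))
             do.call(rbind, ii)
           else data.frame(track_id = integer(0), start_s = numeric(0),
                           end_s = numeric(0), end_cause = character(0)),
           meta = meta),
      class = "ground_truth")
    list(tracks = tracks, truth = truth)
  })
}

#' Extract the visible bound dwell times from a simulation ground truth
#'
#' Converts the bound intervals of a [simulate_two_state_tracks()] ground
#' truth into a dwell sample: durations of visible binding events, censored
#' when the movie ends while the molecule is still bound. Events ending by
#' unbinding or bleaching are observationally identical (the molecule
#' disappears from the slow state) and are both uncensored; separating the
#' two is the job of the photobleach correction.
#'
#' @param truth `ground_truth` from [simulate_two_state_tracks()].
#' @param source Optional source label.
#' @return A [dwell_sample()].
#' @export
dwells_from_truth <- function(truth, source = "simulation") {
  stopifnot(inherits(truth, "ground_truth"))
  iv <- truth$intervals
  if (!nrow(iv)) {
    return(dwell_sample(numeric(0), logical(0), source))
  }
  dwell_sample(iv$end_s - iv$start_s, iv$end_cause == "movie_end", source)
}
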