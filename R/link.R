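# Track linking by per-frame optimal assignment (minimum total squared
# displacement) with gap closing.

# Square linear assignment problem, O(n^3) shortest augmenting path
# (Jonker-Volgonant style with potentials). Returns, for each row, the
# assigned column index. `cost` must be finite (use large values for
# forbidden links).
solve_assignment <- function(cost) {
  n <- nrow(cost)
  if (n == 0L) return(integer(0))
  stopifnot(ncol(cost) == n, all(is.finite(cost)))
  INF <- .Machine$double.xmax / 4
  u <- numeric(n + 1L); v <- numeric(n + 1L)
  p <- integer(n + 1L)  # p[j+1]: row assigned to column j (0 = none)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(INF, n + 1L)
    used <- rep(FALSE, n + 1L)
    way <- integer(n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]; delta <- INF; j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1L]) {
          cur <- cost[i0, j] - u[i0 + 1L] - v[j + 1L]
          if (cur < minv[j + 1L]) { minv[j + 1L] <- cur; way[j + 1L] <- j0 }
          if (minv[j + 1L] < delta) { delta <- minv[j + 1L]; j1 <- j }
        }
      }
      for (j in 0:n) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j + 1L] <- minv[j + 1L] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  ans <- integer(n)
  for (j in seq_len(n)) if (p[j + 1L] > 0L) ans[p[j + 1L]] <- j
  ans
}

#' Link per-frame localizations into tracks
#'
#' Frame-by-frame optimal assignment: each new frame's detections are
#' matched to the ends of active tracks by minimizing total squared
#' displacement, with links forbidden beyond `max_disp * sqrt(gap)` (the
#' diffusive scaling of the search radius over a gap of `gap` frames).
#' Unmatched detections start new tracks; tracks unseen for more than
#' `max_gap` frames are closed. Assignment (not greedy matching) makes the
#' result independent of detection order.
#'
#' @param locs Data frame of localizations with columns `frame` (0-based),
#'   `x_um`, `y_um` (e.g. from [detect_spots_stack()]).
#' @param meta [acquisition_meta()].
#' @param max_disp Maximum per-frame displacement, micrometers.
#' @param max_gap Maximum number of missed frames bridged within a track
#'   (default 0).
#' @return A [track_set()] (additional localization columns are carried
#'   through).
#' @export
link_tracks <- function(locs, meta, max_disp, max_gap = 0L) {
  stopifnot(inherits(meta, "acquisition_meta"))
  if (max_disp <= 0) {
    stop_smkin("max_disp must be positive", "smkin_invalid_parameter")
  }
  locs <- as.data.frame(locs)
  if (!nrow(locs)) {
    return(track_set(data.frame(track_id = integer(0), frame = integer(0),
                                t_s = numeric(0), x_um = numeric(0),
                                y_um = numeric(0)), meta))
  }
  locs <- locs[order(locs$frame), , drop = FALSE]
  locs$track_id <- NA_integer_
  frames <- sort(unique(locs$frame))
  # Active track ends: id, last frame, last x/y.
  act <- data.frame(id = integer(0), frame = integer(0),
                    x = numeric(0), y = numeric(0))
  next_id <- 1L
  BIG <- 1e12
  for (f in frames) {
    rows <- which(locs$frame == f)
    act <- act[f - act$frame <= max_gap + 1L, , drop = FALSE]
    nD <- length(rows); nT <- nrow(act)
    det_x <- locs$x_um[rows]; det_y <- locs$y_um[rows]
    assigned_track <- rep(NA_integer_, nD)
    if (nT > 0L && nD > 0L) {
      gap <- f - act$frame
      allowed2 <- (max_disp^2) * gap  # (max_disp*sqrt(gap))^2
      d2 <- outer(act$x, det_x, function(a, b) (a - b)^2) +
            outer(act$y, det_y, function(a, b) (a - b)^2)
      link_cost <- ifelse(d2 <= allowed2, d2, BIG)
      cap <- max_disp^2
      n <- nT + nD
      cost <- matrix(0, n, n)
      cost[seq_len(nT), seq_len(nD)] <- link_cost
      cost[seq_len(nT), nD + seq_len(nT)] <- BIG    # track death
      cost[cbind(seq_len(nT), nD + seq_len(nT))] <- cap
      cost[nT + seq_len(nD), seq_len(nD)] <- BIG    # detection birth
      cost[cbind(nT + seq_len(nD), seq_len(nD))] <- cap
      sol <- solve_assignment(cost)
      for (ti in seq_len(nT)) {
        j <- sol[ti]
        if (j <= nD && link_cost[ti, j] < BIG) assigned_track[j] <- ti
      }
    }
    new_act <- act
    for (k in seq_len(nD)) {
      ti <- assigned_track[k]
      if (!is.na(ti)) {
        id <- act$id[ti]
      } else {
        id <- next_id; next_id <- next_id + 1L
        new_act <- rbind(new_act,
                         data.frame(id = id, frame = f,
                                    x = det_x[k], y = det_y[k]))
      }
      locs$track_id[rows[k]] <- id
      ai <- which(new_act$id == id)
      new_act$frame[ai] <- f
      new_act$x[ai] <- det_x[k]; new_act$y[ai] <- det_y[k]
    }
    act <- new_act
  }
  locs$t_s <- locs$frame * meta$frame_interval
  ord <- order(locs$track_id, locs$frame)
  locs <- locs[ord, , drop = FALSE]
  rownames(locs) <- NULL
  front <- c("track_id", "frame", "t_s", "x_um", "y_um")
  locs <- locs[, c(front, setdiff(names(locs), front)), drop = FALSE]
  track_set(locs, meta)
}
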