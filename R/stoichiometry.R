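# ZAP70 recruitment stoichiometry: integrate second-channel intensity at
# ligand anchor positions, calibrate against single-molecule intensity,
# convert to molecule counts.

#' Integrate second-channel intensity around anchor tracks
#'
#' For every anchor track, maps each anchor position into the second
#' channel and sums background-subtracted counts over a square window of
#' side `window_um` (315 nm = exactly 3 pixels at 105 nm/px) centered on
#' the mapped position. Background is the per-frame median of an annulus
#' (inner radius 3 px, outer 6 px) around the anchor. Frames missing from
#' the anchor track yield `NA`; anchors whose window leaves the field mark
#' the trace `partial`.
#'
#' @param stack_ch2 Second-channel `frame_stack` (array `[y, x, frame]`).
#' @param anchors A [track_set()] of anchor positions (first channel).
#' @param map A `channel_map` from channel 1 to channel 2 (default
#'   identity).
#' @param window_um Integration window side, micrometers (default 0.315);
#'   must span an odd number of pixels.
#' @param annulus_px Inner/outer background annulus radii in pixels
#'   (default `c(3, 6)`).
#' @return Named list of [intensity_trace()] objects (one per anchor
#'   track id), each with attribute `partial`.
#' @export
integrate_local_intensity <- function(stack_ch2, anchors,
                                      map = identity_channel_map(),
                                      window_um = 0.315,
                                      annulus_px = c(3L, 6L)) {
  stopifnot(inherits(anchors, "track_set"))
  meta <- track_meta(anchors)
  px <- meta$pixel_size
  half_px <- round((window_um / px - 1) / 2)
  if (abs(window_um / px - (2 * half_px + 1)) > 1e-6) {
    stop_smkin(sprintf(
      "window_um = %g um is not an odd pixel span at %g um/px",
      window_um, px), "smkin_invalid_parameter")
  }
  ny <- dim(stack_ch2)[1]; nx <- dim(stack_ch2)[2]; nf <- dim(stack_ch2)[3]
  df <- as.data.frame(anchors)
  out <- list()
  for (tid in unique(df$track_id)) {
    tr <- df[df$track_id == tid, , drop = FALSE]
    tr <- tr[order(tr$frame), , drop = FALSE]
    frames <- tr$frame[1]:tr$frame[nrow(tr)]
    vals <- rep(NA_real_, length(frames))
    partial <- FALSE
    mapped <- apply_channel_map(map, cbind(tr$x_um, tr$y_um))
    for (i in seq_len(nrow(tr))) {
      f <- tr$frame[i]
      if (f < 0L || f >= nf) next
      cx <- round(mapped[i, 1L] / px); cy <- round(mapped[i, 2L] / px)
      x0 <- cx - half_px; x1 <- cx + half_px
      y0 <- cy - half_px; y1 <- cy + half_px
      if (x0 < 0L || y0 < 0L || x1 >= nx || y1 >= ny) {
        partial <- TRUE
        next
      }
      frame_img <- stack_ch2[, , f + 1L]
      bg <- annulus_median(frame_img, cx, cy, annulus_px[1], annulus_px[2])
      win <- frame_img[(y0:y1) + 1L, (x0:x1) + 1L]
      vals[match(f, frames)] <- sum(win - bg)
    }
    tr_out <- intensity_trace(frames * meta$frame_interval, vals)
    attr(tr_out, "partial") <- partial
    out[[as.character(tid)]] <- tr_out
  }
  out
}

# Median of pixels with r_in < distance <= r_out from (cx, cy), 0-based.
annulus_median <- function(img, cx, cy, r_in, r_out) {
  ny <- nrow(img); nx <- ncol(img)
  x0 <- max(0L, cx - r_out); x1 <- min(nx - 1L, cx + r_out)
  y0 <- max(0L, cy - r_out); y1 <- min(ny - 1L, cy + r_out)
  xs <- x0:x1; ys <- y0:y1
  d2 <- outer((ys - cy)^2, (xs - cx)^2, `+`)
  sel <- d2 > r_in^2 & d2 <= r_out^2
  vals <- img[ys + 1L, xs + 1L][sel]
  if (!length(vals)) return(0)
  stats::median(vals)
}

#' Calibrate the single-molecule unit intensity
#'
#' Averages the pre-bleach level of verified single-molecule traces (one
#' downward step to background, no upward steps, as judged by
#' [count_photobleach_steps()]); traces failing the single-molecule test
#' (e.g. two-step bleaching dimers) are rejected and reported.
#'
#' @param traces List of [intensity_trace()] objects.
#' @param cps Optional list of matching [change_point_set()]s; computed
#'   with [detect_change_points()] when omitted.
#' @param background_level Background, counts (default 0).
#' @return List with `unit` (counts/molecule), `sem`, `n` (traces used)
#'   and `rejected` (indices of non-single-molecule traces).
#' @export
calibrate_single_molecule_intensity <- function(traces, cps = NULL,
                                                background_level = 0) {
  if (!length(traces)) {
    stop_smkin("no traces supplied for calibration", "smkin_no_events")
  }
  if (is.null(cps)) cps <- lapply(traces, detect_change_points)
  levels <- numeric(0); rejected <- integer(0)
  for (i in seq_along(traces)) {
    ct <- count_photobleach_steps(cps[[i]], background_level)
    if (ct$is_single_molecule) {
      levels <- c(levels, cps[[i]]$levels[1L])
    } else {
      rejected <- c(rejected, i)
    }
  }
  if (!length(levels)) {
    stop_smkin("no qualifying single-molecule traces", "smkin_no_events")
  }
  list(unit = mean(levels),
       sem = if (length(levels) > 1L) stats::sd(levels) / sqrt(length(levels))
             else NA_real_,
       n = length(levels),
       rejected = rejected)
}

#' Convert feature intensity to molecule counts
#'
#' Visible molecules per feature are the mean feature intensity divided by
#' the single-molecule unit intensity; the total count divides further by
#' the labeled fraction (e.g. 0.5 when the tagged protein is expressed 1:1
#' with its endogenous counterpart). SEMs propagate to first order:
#' `rel_sem(n_visible)^2 = rel_sem(feature)^2 + rel_sem(unit)^2`.
#' Reported values are also given rounded to two significant figures.
#'
#' @param feature_intensity_mean Mean per-frame feature intensity, counts.
#' @param unit Single-molecule intensity, counts/molecule (> 0).
#' @param labeled_fraction Fraction of molecules carrying the label,
#'   in (0, 1] (default 0.5).
#' @param feature_sem,unit_sem SEMs of the two intensities (default 0).
#' @return Object of class `stoichiometry_result` with `unit_intensity`,
#'   `feature_intensity`, `n_visible`, `n_visible_sem`, `n_total`,
#'   `n_total_sem`, `labeled_fraction`, plus `n_visible_2sf`/`n_total_2sf`.
#' @examples
#' estimate_stoichiometry(136.0, 47)  # 2.9 visible, ~5.8 total
#' @export
estimate_stoichiometry <- function(feature_intensity_mean, unit,
                                   labeled_fraction = 0.5,
                                   feature_sem = 0, unit_sem = 0) {
  if (!is.numeric(unit) || unit <= 0) {
    stop_smkin("unit intensity must be positive", "smkin_invalid_parameter")
  }
  if (labeled_fraction <= 0 || labeled_fraction > 1) {
    stop_smkin("labeled_fraction must be in (0, 1]", "smkin_invalid_parameter")
  }
  n_vis <- feature_intensity_mean / unit
  rel <- sqrt((feature_sem / feature_intensity_mean)^2 + (unit_sem / unit)^2)
  n_vis_sem <- abs(n_vis) * rel
  n_tot <- n_vis / labeled_fraction
  structure(list(unit_intensity = unit,
                 feature_intensity = feature_intensity_mean,
                 n_visible = n_vis,
                 n_visible_sem = n_vis_sem,
                 n_total = n_tot,
                 n_total_sem = n_vis_sem / labeled_fraction,
                 labeled_fraction = labeled_fraction,
                 n_visible_2sf = signif2(n_vis),
                 n_total_2sf = signif2(n_tot)),
            class = "stoichiometry_result")
}

#' @export
print.stoichiometry_result <- function(x, ...) {
  cat(sprintf(
    "<stoichiometry_result> %.4g counts / %.4g counts per molecule = %.2g visible; %.2g total at labeled fraction %.2g\n",
    x$feature_intensity, x$unit_intensity, x$n_visible_2sf,
    x$n_total_2sf, x$labeled_fraction))
  invisible(x)
}
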