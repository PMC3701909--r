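# Shared fixtures built in code.

meta_short <- function(n_frames = 200L, field = 64L) {
  acquisition_meta(frame_interval = 0.0175, n_frames = n_frames,
                   field_size = field)
}

meta_long <- function(n_frames = 200L, field = 64L, exposure = 0.05) {
  acquisition_meta(frame_interval = 0.5, exposure_time = exposure,
                   field_size = field, n_frames = n_frames)
}

# Stationary-emitter track set at given positions (um).
stationary_tracks <- function(xy, meta, state = "BOUND") {
  rows <- lapply(seq_len(nrow(xy)), function(i) {
    data.frame(track_id = i, frame = 0:(meta$n_frames - 1L),
               t_s = (0:(meta$n_frames - 1L)) * meta$frame_interval,
               x_um = xy[i, 1], y_um = xy[i, 2], state = state)
  })
  track_set(do.call(rbind, rows), meta)
}

# Match each truth sample to the nearest detection/labelled sample in the
# same frame; returns data.frame(truth_state, label, dist).
match_labels <- function(truth_df, labelled_df, radius = 0.45) {
  by_frame <- split(labelled_df, labelled_df$frame)
  out <- vector("list", nrow(truth_df))
  for (i in seq_len(nrow(truth_df))) {
    cand <- by_frame[[as.character(truth_df$frame[i])]]
    if (is.null(cand)) next
    d <- sqrt((cand$x_um - truth_df$x_um[i])^2 +
              (cand$y_um - truth_df$y_um[i])^2)
    j <- which.min(d)
    if (d[j] <= radius) {
      out[[i]] <- data.frame(truth_state = truth_df$state[i],
                             label = cand$mobility[j], dist = d[j])
    }
  }
  out <- Filter(Negate(is.null), out)
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}
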