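#' Construct an intensity trace
#'
#' Per-frame integrated, background-subtracted camera counts for one
#' diffraction-limited feature.
#'
#' @param t_s Frame times, seconds, strictly increasing.
#' @param counts Background-subtracted counts, same length.
#' @param background_mean,background_sd Background statistics used for the
#'   subtraction (counts); kept for provenance.
#' @return Data frame of class `intensity_trace` with columns `t_s`,
#'   `counts`.
#' @export
intensity_trace <- function(t_s, counts, background_mean = 0,
                            background_sd = 0) {
  if (length(t_s) != length(counts)) {
    stop_smkin("t_s and counts must have equal length", "smkin_schema")
  }
  if (length(t_s) > 1L && any(diff(t_s) <= 0)) {
    stop_smkin("t_s must be strictly increasing", "smkin_schema")
  }
  structure(data.frame(t_s = t_s, counts = counts),
            background_mean = background_mean,
            background_sd = background_sd,
            class = c("intensity_trace", "data.frame"))
}

#' Simulate a stepwise single-molecule intensity trace
#'
#' Builds a piecewise-constant fluorescence trace — e.g. a photobleaching
#' staircase of `m` fluorophores stepping `m*u, (m-1)*u, ..., 0` counts, or
#' a recruitment trace with upward steps — sampled at the frame interval
#' with additive Gaussian camera noise. The true change-point frames and
#' segment levels are returned as ground truth for the change-point
#' detector.
#'
#' @param segment_levels Mean level of each segment, counts.
#' @param segment_durations Duration of each segment, seconds (> 0).
#' @param noise_sd Gaussian noise SD per frame, counts (>= 0).
#' @param meta [acquisition_meta()] supplying the frame interval.
#' @param seed Integer seed.
#' @return List with `trace` ([intensity_trace()]) and `truth` (list with
#'   `change_frames`, 0-based first frame of each new segment, and
#'   `levels`).
#' @examples
#' meta <- acquisition_meta(frame_interval = 0.05, n_frames = 10)
#' sim <- simulate_intensity_trace(c(47, 0), c(3, 3), noise_sd = 5,
#'                                 meta = meta, seed = 1)
#' sim$truth$change_frames
#' @export
simulate_intensity_trace <- function(segment_levels, segment_durations,
                                     noise_sd, meta, seed = NULL) {
  stopifnot(inherits(meta, "acquisition_meta"))
  if (length(segment_levels) == 0L) {
    stop_smkin("segment_levels must be non-empty", "smkin_invalid_parameter")
  }
  if (length(segment_levels) != length(segment_durations)) {
    stop_smkin("segment_levels and segment_durations must have equal length",
               "smkin_invalid_parameter")
  }
  if (any(segment_durations <= 0)) {
    stop_smkin("segment_durations must be positive", "smkin_invalid_parameter")
  }
  if (noise_sd < 0) {
    stop_smkin("noise_sd must be >= 0", "smkin_invalid_parameter")
  }
  dt <- meta$frame_interval
  bounds <- cumsum(segment_durations)
  t_s <- seq(0, sum(segment_durations) - dt / 2, by = dt)
  seg <- findInterval(t_s, c(0, bounds[-length(bounds)]))
  mu <- segment_levels[seg]
  counts <- with_seed(seed, mu + stats::rnorm(length(mu), 0, noise_sd))
  change_frames <- which(diff(seg) != 0)  # 0-based first frame of new segment
  list(trace = intensity_trace(t_s, counts),
       truth = list(change_frames = change_frames,
                    levels = segment_levels,
                    segment_of_frame = seg))
}

#' Simulate photobleaching lifetimes with right censoring
#'
#' Draws exponential single-fluorophore survival times with mean `tau_bl`,
#' right-censored at the movie length `t_max`. This is the synthetic
#' counterpart of measuring a bilayer bleaching standard to calibrate the
#' photobleaching rate used in the dwell-time correction.
#'
#' @param tau_bl Mean bleaching time, seconds (> 0).
#' @param n Number of fluorophores.
#' @param t_max Censoring time, seconds (`Inf` for none).
#' @param seed Integer seed.
#' @return A [dwell_sample()]; censored entries have duration `t_max`.
#' @export
simulate_bleaching_survival <- function(tau_bl, n, t_max = Inf, seed = NULL) {
  if (!is.numeric(tau_bl) || tau_bl <= 0) {
    stop_smkin("tau_bl must be positive", "smkin_invalid_parameter")
  }
  if (!is_count(n)) {
    stop_smkin("n must be a positive integer", "smkin_invalid_parameter")
  }
  if (t_max < 0) {
    stop_smkin("t_max must be >= 0", "smkin_invalid_parameter")
  }
  with_seed(seed, {
    life <- stats::rexp(n, rate = 1 / tau_bl)
    cens <- life > t_max
    dwell_sample(pmin(life, t_max), cens, source = "bleach_standard")
  })
}
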