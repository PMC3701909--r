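#' Change points of an intensity trace
#'
#' Container for the result of [detect_change_points()]: 0-based frame
#' indices at which the mean level shifts (each index is the first frame of
#' the new segment), the posterior-mean level of every segment, and the
#' log10 odds supporting each accepted change.
#'
#' @param change_frames Integer vector, strictly increasing, 0-based.
#' @param levels Numeric vector of segment levels, `length(change_frames) + 1`.
#' @param log_odds Numeric vector, one entry per change.
#' @param noise_sd Estimated per-frame noise SD, counts.
#' @param n_frames Trace length.
#' @return Object of class `change_point_set`.
#' @export
change_point_set <- function(change_frames, levels, log_odds, noise_sd,
                             n_frames) {
  if (length(change_frames) > 1L && any(diff(change_frames) <= 0)) {
    stop_smkin("change_frames must be strictly increasing", "smkin_schema")
  }
  if (length(levels) != length(change_frames) + 1L) {
    stop_smkin("levels must have one more entry than change_frames",
               "smkin_schema")
  }
  structure(list(change_frames = as.integer(change_frames),
                 levels = as.numeric(levels),
                 log_odds = as.numeric(log_odds),
                 noise_sd = noise_sd,
                 n_frames = as.integer(n_frames)),
            class = "change_point_set")
}

#' @export
print.change_point_set <- function(x, ...) {
  cat(sprintf("<change_point_set> %d change(s) over %d frames; levels: %s\n",
              length(x$change_frames), x$n_frames,
              paste(signif(x$levels, 4), collapse = " -> ")))
  invisible(x)
}

# Log marginal likelihood of a constant-mean Gaussian segment under the
# reference prior p(mu, sigma^2) ~ 1/sigma^2:
#   m(y) = pi^-((n-1)/2) n^-1/2 Gamma((n-1)/2) SS^-((n-1)/2),
# SS the centered sum of squares. SS is floored to keep noiseless segments
# finite; the floor cancels for comparisons on the same data scale.
log_marginal_segment <- function(n, ss, ss_floor) {
  ss <- max(ss, ss_floor)
  -((n - 1) / 2) * log(pi) - 0.5 * log(n) + lgamma((n - 1) / 2) -
    ((n - 1) / 2) * log(ss)
}

# Best single change point of y (numeric vector, length >= 2*min_seg).
# Returns list(k = 1-based last index of left segment, log_odds base 10).
best_split <- function(y, min_seg, ss_floor) {
  n <- length(y)
  s1 <- cumsum(y); s2 <- cumsum(y^2)
  tot1 <- s1[n]; tot2 <- s2[n]
  ss_all <- tot2 - tot1^2 / n
  m0 <- log_marginal_segment(n, ss_all, ss_floor)
  ks <- min_seg:(n - min_seg)
  nl <- ks; nr <- n - ks
  ssl <- s2[ks] - s1[ks]^2 / nl
  ssr <- (tot2 - s2[ks]) - (tot1 - s1[ks])^2 / nr
  m1 <- vapply(seq_along(ks), function(i) {
    log_marginal_segment(nl[i], ssl[i], ss_floor) +
      log_marginal_segment(nr[i], ssr[i], ss_floor)
  }, numeric(1))
  best <- which.max(m1)  # which.max takes the earliest index on ties
  lo <- (m1[best] - log(length(ks)) - m0) / log(10)
  list(k = ks[best], log_odds = lo)
}

#' Detect intensity steps by Bayesian model comparison
#'
#' Recursive binary segmentation of a single-molecule intensity trace under
#' a Gaussian observation model. At each stage the marginal likelihood of
#' "one mean shift at the best location" (each side with its own mean and
#' variance, reference priors, uniform prior over candidate locations) is
#' compared with "constant mean"; the split is accepted when the log10 odds
#' exceed `log_odds_min` (default 2, "decisive" on the Jeffreys scale), then
#' both sides are segmented recursively. Segment levels are the posterior
#' (= sample) means. Candidate locations keep at least `min_seg` frames on
#' each side; ties break to the earlier index.
#'
#' @param trace An [intensity_trace()] (or data frame with `t_s`, `counts`).
#' @param log_odds_min Acceptance threshold, log10 odds (default 2).
#' @param min_seg Minimum segment length in frames (default 2).
#' @return A [change_point_set()].
#' @examples
#' meta <- acquisition_meta(frame_interval = 0.05, n_frames = 10)
#' sim <- simulate_intensity_trace(c(50, 0), c(5, 5), 4, meta, seed = 2)
#' detect_change_points(sim$trace)
#' @export
detect_change_points <- function(trace, log_odds_min = 2, min_seg = 2L) {
  y <- trace$counts
  n <- length(y)
  if (n < 4L) {
    stop_smkin("trace must have at least 4 frames", "smkin_invalid_parameter")
  }
  scale2 <- mean(y^2)
  ss_floor <- n * 1e-16 * max(1, scale2)
  noise_sd <- estimate_trace_noise(y)

  changes <- integer(0); odds <- numeric(0)
  recurse <- function(lo, hi) {
    len <- hi - lo + 1L
    if (len < 2L * min_seg) return(invisible())
    seg <- y[lo:hi]
    if (stats::var(seg) == 0) return(invisible())  # flat: nothing to split
    sp <- best_split(seg, min_seg, ss_floor)
    if (sp$log_odds >= log_odds_min) {
      k_abs <- lo + sp$k - 1L
      changes <<- c(changes, k_abs)
      odds <<- c(odds, sp$log_odds)
      recurse(lo, k_abs)
      recurse(k_abs + 1L, hi)
    }
    invisible()
  }
  recurse(1L, n)

  ord <- order(changes)
  changes <- changes[ord]; odds <- odds[ord]
  bounds <- c(0L, changes, n)
  levels <- vapply(seq_len(length(bounds) - 1L), function(i) {
    mean(y[(bounds[i] + 1L):bounds[i + 1L]])
  }, numeric(1))
  # `changes` holds the 1-based last index of each left segment, which is
  # the 0-based first frame of the new segment.
  change_point_set(changes, levels, odds, noise_sd, n)
}

# Robust per-trace noise estimate from lag-1 differences (insensitive to a
# few steps): sd = MAD(diff)/sqrt(2).
estimate_trace_noise <- function(y) {
  if (length(y) < 2L) return(0)
  stats::mad(diff(y)) / sqrt(2)
}

#' Count photobleaching steps and classify single-molecule traces
#'
#' Downward level changes are bleaching (or unbinding) steps; upward
#' changes are arrivals (e.g. kinase recruitment) and are reported
#' separately, never as bleach steps. A trace qualifies as a single
#' molecule when it shows exactly one downward step, no upward steps, and
#' its final level sits at background. Two downward steps flag a dimer.
#'
#' @param cps A [change_point_set()].
#' @param background_level Background level, counts (default 0 for
#'   background-subtracted traces).
#' @param tol Tolerance for "at background", counts; default
#'   `3 * cps$noise_sd` (at least 1e-9).
#' @return List with `n_steps` (downward changes), `n_up` (upward changes)
#'   and `is_single_molecule`.
#' @export
count_photobleach_steps <- function(cps, background_level = 0, tol = NULL) {
  stopifnot(inherits(cps, "change_point_set"))
  if (is.null(tol)) tol <- max(3 * cps$noise_sd, 1e-9)
  dl <- diff(cps$levels)
  n_down <- sum(dl < 0)
  n_up <- sum(dl > 0)
  ends_at_bg <- abs(cps$levels[length(cps$levels)] - background_level) <= tol
  list(n_steps = n_down,
       n_up = n_up,
       is_single_molecule = (n_down == 1L && n_up == 0L && ends_at_bg))
}
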