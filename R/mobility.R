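# Step-size analysis: pooled displacement distributions, Rayleigh mixture
# fits, and bound/free segment classification.

#' Pooled step sizes of a track set
#'
#' Collects all displacements at a given frame lag across tracks. Only
#' sample pairs exactly `lag` frames apart contribute (gaps do not produce
#' spurious long steps).
#'
#' @param tracks A [track_set()].
#' @param lag Frame lag (>= 1, default 1).
#' @return Object of class `step_sample`: list with `lag`, `dr`, `dx`,
#'   `dy` (micrometers) and `dt_lag` (seconds).
#' @export
step_size_distribution <- function(tracks, lag = 1L) {
  stopifnot(inherits(tracks, "track_set"))
  if (!is_count(lag)) stop_smkin("lag must be a positive integer",
                                 "smkin_invalid_parameter")
  meta <- track_meta(tracks)
  dx <- dy <- numeric(0)
  for (tr in split(as.data.frame(tracks), tracks$track_id)) {
    o <- order(tr$frame)
    fr <- tr$frame[o]
    j <- match(fr + lag, fr)
    ok <- !is.na(j)
    if (!any(ok)) next
    dx <- c(dx, tr$x_um[o][j[ok]] - tr$x_um[o][ok])
    dy <- c(dy, tr$y_um[o][j[ok]] - tr$y_um[o][ok])
  }
  structure(list(lag = as.integer(lag), dr = sqrt(dx^2 + dy^2),
                 dx = dx, dy = dy,
                 dt_lag = lag * meta$frame_interval),
            class = "step_sample")
}

#' @export
print.step_sample <- function(x, ...) {
  cat(sprintf("<step_sample> %d displacements at lag %d (dt = %.4g s), RMS %.4g um\n",
              length(x$dr), x$lag, x$dt_lag,
              sqrt(mean(x$dr^2))))
  invisible(x)
}

# Rayleigh density with scale s = 2*D*dt: p(r) = r/s * exp(-r^2/(2s)).
drayleigh <- function(r, s) r / s * exp(-r^2 / (2 * s))

#' Fit a two-component Rayleigh mixture to step sizes
#'
#' For isotropic Brownian motion the displacement magnitude at lag time
#' `dt` is Rayleigh: `p(r) = (r / (2 D dt)) exp(-r^2 / (4 D dt))`. A
#' mixture of a slow (bound) and a fast (free) component,
#' `p(r) = f_slow p_slow(r) + f_fast p_fast(r)`, is fitted by EM; a
#' single-component fit is returned instead when it wins by BIC (the
#' unimodal case, e.g. ligand in a bilayer with no cell contact). The
#' classification threshold `r_star` is the step size where the two
#' component posteriors are equal.
#'
#' @param steps A `step_sample` from [step_size_distribution()] (>= 50
#'   displacements).
#' @param dt_lag Lag time in seconds; defaults to the sample's own.
#' @param max_iter,tol EM controls.
#' @return Object of class `mobility_fit`: `n_components`, `f_slow`,
#'   `f_fast`, `d_slow`, `d_fast` (um^2/s), `log_lik`, `bic`, `r_star`
#'   (um; `NA` for one component), `dt_lag`.
#' @export
fit_mobility_mixture <- function(steps, dt_lag = NULL,
                                 max_iter = 500L, tol = 1e-10) {
  stopifnot(inherits(steps, "step_sample"))
  if (is.null(dt_lag)) dt_lag <- steps$dt_lag
  r <- steps$dr[is.finite(steps$dr)]
  r <- r[r >= 0]
  n <- length(r)
  if (n < 50L) {
    stop_smkin("need at least 50 displacements", "smkin_invalid_parameter")
  }
  if (all(r == 0)) {
    stop_smkin("degenerate sample: all displacements zero",
               "smkin_degenerate_sample")
  }
  r <- pmax(r, 1e-12)
  r2 <- r^2

  # One-component MLE: s = mean(r^2)/2.
  s1 <- mean(r2) / 2
  ll1 <- sum(log(drayleigh(r, s1)))
  bic1 <- -2 * ll1 + 1 * log(n)

  # Two-component EM, initialized from the r^2 quantiles.
  qs <- stats::quantile(r2, c(0.25, 0.75), names = FALSE)
  s_lo <- max(qs[1] / 2, 1e-12); s_hi <- max(qs[2] / 2, s_lo * 2)
  f <- 0.5
  ll2 <- -Inf
  for (it in seq_len(max_iter)) {
    p_lo <- f * drayleigh(r, s_lo)
    p_hi <- (1 - f) * drayleigh(r, s_hi)
    tot <- p_lo + p_hi
    tot[tot == 0] <- .Machine$double.xmin
    g <- p_lo / tot
    ll_new <- sum(log(tot))
    f <- mean(g)
    f <- min(max(f, 1e-6), 1 - 1e-6)
    s_lo <- max(sum(g * r2) / (2 * sum(g)), 1e-14)
    s_hi <- max(sum((1 - g) * r2) / (2 * sum(1 - g)), 1e-14)
    if (s_lo > s_hi) {  # keep the slow component first
      tmp <- s_lo; s_lo <- s_hi; s_hi <- tmp; f <- 1 - f
    }
    if (is.finite(ll2) && abs(ll_new - ll2) < tol * (abs(ll2) + 1)) {
      ll2 <- ll_new; break
    }
    ll2 <- ll_new
  }
  bic2 <- -2 * ll2 + 3 * log(n)

  if (bic2 < bic1 && s_hi / s_lo > 1.0001) {
    d_slow <- s_lo / (2 * dt_lag); d_fast <- s_hi / (2 * dt_lag)
    # Posterior equality: f p_lo(r*) = (1-f) p_hi(r*).
    num <- log(f / s_lo) - log((1 - f) / s_hi)
    den <- 1 / (2 * s_lo) - 1 / (2 * s_hi)
    r_star <- if (num > 0 && den > 0) sqrt(num / den) else sqrt(2 * s_lo)
    structure(list(n_components = 2L, f_slow = f, f_fast = 1 - f,
                   d_slow = d_slow, d_fast = d_fast,
                   log_lik = ll2, bic = bic2, r_star = r_star,
                   dt_lag = dt_lag),
              class = "mobility_fit")
  } else {
    structure(list(n_components = 1L, f_slow = 0, f_fast = 1,
                   d_slow = NA_real_, d_fast = s1 / (2 * dt_lag),
                   log_lik = ll1, bic = bic1, r_star = NA_real_,
                   dt_lag = dt_lag),
              class = "mobility_fit")
  }
}

#' @export
print.mobility_fit <- function(x, ...) {
  if (x$n_components == 2L) {
    cat(sprintf(
      "<mobility_fit> 2 components: D_slow = %.4g (f = %.3f), D_fast = %.4g um^2/s; r* = %.4g um\n",
      x$d_slow, x$f_slow, x$d_fast, x$r_star))
  } else {
    cat(sprintf("<mobility_fit> 1 component: D = %.4g um^2/s\n", x$d_fast))
  }
  invisible(x)
}

# Threshold on the windowed mean squared step separating slow from fast.
# The squared displacement of a Rayleigh step with scale s is exponential
# with mean 2s; the mean of k such terms is Gamma(k, scale 2s/k), and the
# posterior-equality crossing of the two weighted Gamma densities is
#   M* = [k log(theta_hi/theta_lo) + log(f_slow/f_fast)] /
#        (k (1/theta_lo - 1/theta_hi)),  theta_i = 2 s_i.
# Falls back to the geometric mean of the two component MSDs when the
# crossing is outside (theta_lo, theta_hi).
msd_threshold <- function(f_slow, s_lo, s_hi, k) {
  th_lo <- 2 * s_lo; th_hi <- 2 * s_hi
  num <- k * log(th_hi / th_lo) + log(f_slow / (1 - f_slow))
  den <- k * (1 / th_lo - 1 / th_hi)
  m <- num / den
  if (!is.finite(m) || m <= th_lo / 4 || m >= th_hi) sqrt(th_lo * th_hi) else m
}

#' Classify bound (slow) and free (fast) track segments
#'
#' Labels each track sample by comparing the windowed *median* squared
#' per-frame displacement with the crossing point of the two mixture
#' components' squared-step densities (the squared step of a diffusing
#' molecule is exponential, so the crossing has a closed form). The median
#' makes a label robust to a single corrupted step — e.g. a transient
#' overlap with a passing molecule — which would otherwise fragment long
#' dwells. Below the threshold means `BOUND`, at or above means `FREE`
#' (ties break toward `FREE`, conservative for dwell times). Maximal runs of `BOUND` frames become
#' dwell events; an event is censored when it touches the start or end of
#' the movie, and uncensored when the molecule reverts to fast motion or
#' disappears (disappearance is unbinding-or-bleaching, resolved later by
#' the photobleach correction). Tracks shorter than `window + 1` samples
#' are labeled `UNKNOWN` and excluded.
#'
#' @param tracks A [track_set()].
#' @param fit A 2-component `mobility_fit`.
#' @param window Smoothing window in steps (default 3).
#' @param r_star Optional explicit threshold, um, overriding `fit`: samples
#'   whose windowed RMS step is below `r_star` are `BOUND`.
#' @param edge_margin_um Dwell events whose mean position lies within this
#'   distance (um) of the field edge are discarded (default 0): point
#'   spread functions clipped at the camera border make detection — and
#'   therefore dwell persistence — unreliable there.
#' @return List with `tracks` (the input with a `mobility` column) and
#'   `dwells` (a [dwell_sample()]).
#' @export
classify_bound_segments <- function(tracks, fit = NULL, window = 3L,
                                    r_star = NULL, edge_margin_um = 0) {
  stopifnot(inherits(tracks, "track_set"))
  if (!is_count(window)) stop_smkin("window must be a positive integer",
                                    "smkin_invalid_parameter")
  if (is.null(r_star)) {
    stopifnot(inherits(fit, "mobility_fit"))
    if (fit$n_components != 2L || !is.finite(fit$r_star)) {
      stop_smkin("mobility fit has no bound component to classify against",
                 "smkin_invalid_parameter")
    }
    s_lo <- 2 * fit$d_slow * fit$dt_lag
    s_hi <- 2 * fit$d_fast * fit$dt_lag
    thr <- msd_threshold(fit$f_slow, s_lo, s_hi, 1L)
  } else {
    thr <- r_star^2
  }
  meta <- track_meta(tracks)
  nf <- meta$n_frames
  df <- as.data.frame(tracks)
  df$mobility <- "UNKNOWN"
  durations <- numeric(0); censored <- logical(0)
  half <- (window - 1L) %/% 2L
  for (tid in unique(df$track_id)) {
    rows <- which(df$track_id == tid)
    o <- rows[order(df$frame[rows])]
    m <- length(o)
    if (m < window + 1L) next
    fr <- df$frame[o]
    d2 <- diff(df$x_um[o])^2 + diff(df$y_um[o])^2
    gap <- diff(fr)
    msd_eq <- d2 / gap  # per-frame-equivalent squared step over gaps
    lab <- character(m)
    n_steps <- m - 1L
    for (i in seq_len(m)) {
      # Steps i-1 and i flank sample i; center a window of `window` steps.
      lo <- i - 1L - half
      hi <- lo + window - 1L
      if (lo < 1L) { lo <- 1L; hi <- min(n_steps, window) }
      if (hi > n_steps) { hi <- n_steps; lo <- max(1L, hi - window + 1L) }
      mu <- stats::median(msd_eq[lo:hi])
      lab[i] <- if (mu < thr) "BOUND" else "FREE"
    }
    df$mobility[o] <- lab
    # Dwell events from maximal BOUND runs.
    rl <- rle(lab == "BOUND")
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    ext <- field_extent_um(meta)
    for (k in seq_along(rl$values)) {
      if (!rl$values[k]) next
      if (edge_margin_um > 0) {
        mx <- mean(df$x_um[o][starts[k]:ends[k]])
        my <- mean(df$y_um[o][starts[k]:ends[k]])
        if (min(mx, my, ext[1] - mx, ext[2] - my) < edge_margin_um) next
      }
      f0 <- fr[starts[k]]; f1 <- fr[ends[k]]
      dur <- (f1 - f0 + 1L) * meta$frame_interval
      cens <- (f0 == 0L) || (f1 == nf - 1L)
      durations <- c(durations, dur)
      censored <- c(censored, cens)
    }
  }
  out <- track_set(df, meta)
  list(tracks = out,
       dwells = dwell_sample(durations, censored, source = "classified"))
}
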